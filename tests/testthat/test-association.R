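test_that("the odds ratio follows the 2x2 definition with exact p-values", {
  r <- odds_ratio_test(10, 90, 10, 90)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  expect_equal(odds_ratio_test(20, 80, 10, 90)$odds_ratio, 2.25)
  # frozen enumeration oracle: margins (4, 4), observed a = 3
  expect_equal(odds_ratio_test(3, 1, 1, 3)$p, 34 / 70, tolerance = 1e-12)
  # zero cells: infinite OR, Haldane-corrected CI
  inf <- odds_ratio_test(5, 0, 2, 8)
  expect_identical(inf$odds_ratio, Inf)
  expect_true(is.finite(inf$ci_low) && is.finite(inf$ci_high))
  expect_error(odds_ratio_test(0, 0, 1, 1), "margin")
  # lineage-swap antisymmetry on the log scale
  set.seed(7)
  for (i in 1:20) {
    t <- sample(1:30, 4, replace = TRUE)
    o1 <- odds_ratio_test(t[1], t[2], t[3], t[4])$odds_ratio
    o2 <- odds_ratio_test(t[3], t[4], t[1], t[2])$odds_ratio
    expect_equal(log(o1) + log(o2), 0, tolerance = 1e-12)
  }
  # CI brackets the estimate for all-positive tables
  set.seed(8)
  for (i in 1:20) {
    t <- sample(1:40, 4, replace = TRUE)
    r <- odds_ratio_test(t[1], t[2], t[3], t[4])
    expect_lte(r$ci_low, r$odds_ratio)
    expect_gte(r$ci_high, r$odds_ratio)
  }
})

test_that("exact p matches the independent enumeration oracle on random tables", {
  set.seed(11)
  for (i in 1:200) {
    t <- sample(0:25, 4, replace = TRUE)
    if (t[1] + t[2] == 0 || t[3] + t[4] == 0) next
    expect_equal(odds_ratio_test(t[1], t[2], t[3], t[4])$p,
                 oracle_fisher_p2(t[1], t[2], t[3], t[4]), tolerance = 1e-9)
  }
})

test_that("feature enumeration partitions each lineage and respects scope", {
  gen <- generate_repertoire(sim_config(n_cells = 2000, seed = 13))
  cells <- filter_cells(gen$cells)
  paired <- deduplicate(cells, "paired")
  alpha <- project_repertoire(paired, "alpha")
  fc <- enumerate_features(alpha, "v_gene")
  n4 <- sum(alpha$lineage == "CD4")
  expect_equal(sum(fc$a), n4)
  expect_true(all(fc$a + fc$b == n4))
  # v_pair cardinality bounded by the gene universe product
  fp <- enumerate_features(paired, "v_pair")
  expect_lte(nrow(fp), 30 * 40)
  expect_equal(sum(fp$a), sum(paired$lineage == "CD4"))
  # scope mismatches error
  expect_error(enumerate_features(paired, "v_gene"), "single-chain")
  expect_error(enumerate_features(alpha, "v_pair"), "paired")
  # J features demand a J-keyed deduplication
  expect_error(enumerate_features(alpha, "j_gene"), "include_j")
  alpha_j <- project_repertoire(deduplicate(cells, "paired", include_j = TRUE), "alpha")
  attr(alpha_j, "include_j") <- TRUE
  expect_gt(nrow(enumerate_features(alpha_j, "j_gene")), 0)
})

test_that("charge features pool sparse values into tails", {
  cdr3 <- c(rep("CAKKF", 30), rep("CASSF", 30), rep("CADDF", 30),
            "CAKKKKKF", "CADDDDDF")  # charges 2, 0, -2, 5, -5 (sparse extremes)
  cells <- tibble::tibble(
    cell_id = sprintf("c%d", seq_along(cdr3)), subject = "S1",
    lineage = rep(c("CD4", "CD8"), length.out = length(cdr3)),
    v_a = sprintf("TRAV%d", seq_along(cdr3)), j_a = "TRAJ1", cdr3_a = cdr3,
    v_b = "TRBV1", j_b = "TRBJ1", cdr3_b = "CASSF",
    n_alpha_chains = 1L, n_beta_chains = 1L
  )
  fc <- enumerate_features(deduplicate(cells, "alpha"), "charge")
  expect_true(any(grepl("^<=", fc$feature)))
  expect_true(any(grepl("^>=", fc$feature)))
  # each retained bin holds at least 10 observations in total
  expect_true(all(fc$a + fc$c >= 10))
})

test_that("association scans adjust p-values per family and are order-invariant", {
  gen <- generate_repertoire(sim_config(n_cells = 4000, seed = 23))
  cells <- filter_cells(gen$cells)
  paired <- deduplicate(cells, "paired")
  alpha <- project_repertoire(paired, "alpha")
  scan <- association_scan(alpha, "v_gene")
  expect_s3_class(scan, "tcr_scan")
  expect_equal(attr(scan, "adjust_method"), "bonferroni")
  expect_true(all(scan$adjusted >= scan$p))
  expect_equal(scan$adjusted, pmin(scan$p * nrow(scan), 1))
  ps <- association_scan(paired, "v_pair")
  expect_equal(attr(ps, "adjust_method"), "qvalue")
  expect_true(all(ps$adjusted >= ps$p - 1e-12))
  # row order of the input must not matter
  shuffled <- structure(tibble::as_tibble(paired)[sample(nrow(paired)), ],
                        scope = "paired", class = class(paired))
  ps2 <- association_scan(shuffled, "v_pair")
  expect_equal(dplyr::arrange(tibble::as_tibble(ps), feature),
               dplyr::arrange(tibble::as_tibble(ps2), feature))
  # Bonferroni multiplication rule
  expect_equal(pmin(0.004 * 10, 1), 0.04)
})

test_that("q-values reduce to BH for small families and keep order", {
  set.seed(41)
  p <- c(runif(50, 0, 0.01), runif(450))
  q_small <- tcrpair:::storey_qvalue(p[1:50])
  expect_equal(q_small, p.adjust(p[1:50], "BH"))
  q <- tcrpair:::storey_qvalue(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # Storey q-values are no larger than BH (pi0 <= 1)
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
})

test_that("amino-acid usage ratio test handles null, shifted, and degenerate input", {
  base <- function(subject, lineage, seqs) {
    tibble::tibble(
      cell_id = paste0(subject, lineage, seq_along(seqs)), subject = subject,
      lineage = lineage, v_a = sprintf("TRAV%d", seq_along(seqs)), j_a = "TRAJ1",
      cdr3_a = seqs, v_b = sprintf("TRBV%d", seq_along(seqs)), j_b = "TRBJ1",
      cdr3_b = seqs, n_alpha_chains = 1L, n_beta_chains = 1L
    )
  }
  seqs <- c("CAKSF", "CADTF", "CAGYF", "CAWPF")
  null_cells <- dplyr::bind_rows(lapply(c("S1", "S2", "S3"), function(s) {
    dplyr::bind_rows(base(s, "CD4", seqs), base(s, "CD8", seqs))
  }))
  # amino acids absent from every CDR3 yield undefined ratios (warned)
  res <- suppressWarnings(aa_usage_ratio_test(null_cells, "alpha"))
  seen <- res[res$n_subjects >= 2 & !is.na(res$p), ]
  expect_true(all(abs(seen$mean_ratio - 1) < 1e-12))
  expect_true(all(seen$p == 1))
  expect_true(all(seen$zero_variance))
  # a consistent CD4 enrichment of K across subjects is detected
  shifted <- dplyr::bind_rows(lapply(1:4, function(i) {
    cd4 <- c("CAKKKF", "CAKKTF", "CAKGYF", sprintf("CAW%sF", strrep("P", i)))
    cd8 <- c("CAKSSF", "CADTTF", "CAGYYF", sprintf("CAW%sF", strrep("S", i)))
    dplyr::bind_rows(base(paste0("S", i), "CD4", cd4), base(paste0("S", i), "CD8", cd8))
  }))
  expect_warning(res2 <- aa_usage_ratio_test(shifted, "alpha"))
  expect_lt(res2$p[res2$aa == "K"], 0.05)
  expect_error(aa_usage_ratio_test(base("S1", "CD4", seqs), "alpha"), "subjects")
})

test_that("strength comparison contrasts significant |log OR| distributions", {
  mk_scan <- function(or) {
    tibble::tibble(feature = sprintf("f%d", seq_along(or)),
                   a = 10L, b = 10L, c = 10L, d = 10L,
                   odds_ratio = or, ci_low = or / 2, ci_high = or * 2,
                   p = 1e-6, adjusted = 1e-5, significant = TRUE)
  }
  set.seed(5)
  single <- mk_scan(exp(abs(rnorm(40, 0.3, 0.05))))
  paired <- mk_scan(exp(abs(rnorm(40, 1.2, 0.1))))
  res <- strength_comparison(single, paired, "CD4")
  expect_true(res$applicable)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$median_paired, res$median_single)
  # identical distributions: p near 1
  res0 <- strength_comparison(single, single, "CD4")
  expect_gt(res0$p_value, 0.9)
  # empty selection: not-applicable record
  none <- mk_scan(0.5)  # CD8-biased, so nothing in the CD4 direction
  resNA <- strength_comparison(none, paired, "CD4")
  expect_false(resNA$applicable)
  expect_true(is.na(resNA$p_value))
})
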