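fixture_db <- function() {
  tibble::tibble(
    gene = c("TRAV1", "TRAV1", "TRBV5", "TRBV6", "TRAV2", "TRBV7"),
    cdr3 = c("CAVMDSSYKLIF", "CAVMDSSYKLIF", "CASSLGETQYF", "CASSPGQGF",
             "CAGGGNKLTF", "CASSIRSSYEQYF"),
    epitope = c("NLVPMVATV", "GILGFVFTL", "NLVPMVATV", "GILGFVFTL",
                "GLCTLVAML", "RAKFKQLL"),
    species = c("CMV", "InfluenzaA", "CMV", "InfluenzaA", "EBV", "EBV"),
    mhc_class = c("I", "I", "I", "I", "I", "I")
  )
}

mk_pairs <- function(v_a, cdr3_a, v_b, cdr3_b, lineage = "CD8") {
  cells <- tibble::tibble(
    cell_id = sprintf("c%d", seq_along(v_a)), subject = "S1", lineage = lineage,
    v_a = v_a, j_a = "TRAJ1", cdr3_a = cdr3_a,
    v_b = v_b, j_b = "TRBJ1", cdr3_b = cdr3_b,
    n_alpha_chains = 1L, n_beta_chains = 1L
  )
  deduplicate(cells, "paired")
}

test_that("the annotation database loads, normalizes, and deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  raw <- fixture_db()
  # VDJdb-dialect column names, an allele suffix, and a duplicate row
  vdj <- tibble::tibble(gene = c(raw$gene, "TRAV1*01"),
                        cdr3 = c(raw$cdr3, "CAVMDSSYKLIF"),
                        `antigen.epitope` = c(raw$epitope, "NLVPMVATV"),
                        `antigen.species` = c(raw$species, "CMV"),
                        `mhc.class` = c(raw$mhc_class, "I"))
  readr::write_tsv(vdj, path)
  db <- load_annotation_db(path)
  expect_equal(nrow(db), 6L)  # duplicate collapsed
  expect_setequal(unique(db$chain), c("alpha", "beta"))
  # one chain key can hold several specificities
  expect_equal(sum(db$gene == "TRAV1" & db$cdr3 == "CAVMDSSYKLIF"), 2L)
  # unknown MHC class is kept with a warning
  odd <- dplyr::mutate(raw, mhc_class = replace(mhc_class, 1, "weird"))
  expect_warning(db2 <- load_annotation_db(odd), "MHC")
  expect_true("unknown" %in% db2$mhc_class)
  expect_error(load_annotation_db(dplyr::select(raw, -cdr3)),
               class = "tcrpair_config_error")
})

test_that("single-chain annotation respects the V + CDR3 key", {
  db <- load_annotation_db(fixture_db())
  rep <- mk_pairs(
    v_a = c("TRAV1", "TRAV2", "TRAV9"),
    cdr3_a = c("CAVMDSSYKLIF", "CAGGGNKLTF", "CAVMDSSYKLIF"),
    v_b = c("TRBV5", "TRBV9", "TRBV9"),
    cdr3_b = c("CASSLGETQYF", "CASSF", "CASSG")
  )
  cov <- annotate_single_chains(rep, db)
  a <- cov[cov$chain == "alpha", ]
  b <- cov[cov$chain == "beta", ]
  # TRAV9 + CAVMDSSYKLIF matches on CDR3 but not V: not annotated
  expect_equal(a$n_annotated, 2L)
  expect_equal(b$n_annotated, 1L)
  expect_equal(a$fraction, 2 / 3)
  species <- attr(cov, "species")
  expect_true("CMV" %in% species$species)
  # empty database: zero coverage
  cov0 <- annotate_single_chains(rep, load_annotation_db(fixture_db()[0, ]))
  expect_true(all(cov0$n_annotated == 0L))
})

test_that("paired concordance classifies pairs with the match precedence", {
  db <- load_annotation_db(fixture_db())
  rep <- mk_pairs(
    v_a = c("TRAV1", "TRAV2", "TRAV1", "TRAV2"),
    cdr3_a = c("CAVMDSSYKLIF", "CAGGGNKLTF", "CAVMDSSYKLIF", "CAGGGNKLTF"),
    v_b = c("TRBV5", "TRBV6", "TRBV7", "TRBV9"),
    cdr3_b = c("CASSLGETQYF", "CASSPGQGF", "CASSIRSSYEQYF", "CASSF")
  )
  conc <- paired_concordance(rep, db)
  # pair 1: alpha {CMV NLV, Flu GIL}, beta {CMV NLV} -> matched (precedence)
  # pair 2: alpha EBV GLC, beta Flu GIL -> different species
  # pair 3: alpha {CMV, Flu}, beta EBV RAK -> different species
  # pair 4: only alpha annotated -> excluded from the tally
  expect_equal(conc$n_both_annotated, 3L)
  got <- setNames(conc$counts$n, conc$counts$status)
  expect_equal(unname(got["matched_epitope"]), 1L)
  expect_equal(unname(got["diff_species"]), 2L)
  expect_equal(sum(conc$counts$n), conc$n_both_annotated)
  expect_equal(sum(conc$pairs$status == "one_annotated"), 1L)
  # species matrix covers the annotated cross-products
  expect_gte(sum(conc$species_matrix$n), 3L)
  # invariant to database and repertoire row order
  db_shuf <- db[sample(nrow(db)), ]
  class(db_shuf) <- class(db)
  rep_shuf <- structure(tibble::as_tibble(rep)[c(3, 1, 4, 2), ],
                        scope = "paired", class = class(rep))
  conc2 <- paired_concordance(rep_shuf, db_shuf)
  expect_equal(dplyr::arrange(conc2$counts, status),
               dplyr::arrange(conc$counts, status))
})

test_that("same-species different-epitope ranks below an epitope match", {
  db <- load_annotation_db(tibble::tibble(
    gene = c("TRAV1", "TRBV5"), cdr3 = c("CAVF", "CASSF"),
    epitope = c("NLVPMVATV", "TPRVTGGGAM"), species = c("CMV", "CMV"),
    mhc_class = c("I", "I")
  ))
  conc <- paired_concordance(mk_pairs("TRAV1", "CAVF", "TRBV5", "CASSF"), db)
  expect_equal(conc$pairs$status, "same_species_diff_epitope")
})

test_that("coverage grows monotonically as database rows are added", {
  rep <- mk_pairs(
    v_a = c("TRAV1", "TRAV2", "TRAV3"),
    cdr3_a = c("CAVMDSSYKLIF", "CAGGGNKLTF", "CAFFF"),
    v_b = c("TRBV5", "TRBV6", "TRBV7"),
    cdr3_b = c("CASSLGETQYF", "CASSPGQGF", "CASSIRSSYEQYF")
  )
  fullest <- fixture_db()
  prev <- -1L
  for (k in c(0, 2, 4, 6)) {
    db <- load_annotation_db(fullest[seq_len(k), ])
    cur <- sum(annotate_single_chains(rep, db)$n_annotated)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("promiscuous alpha chains pairing to different epitopes are flagged", {
  db <- load_annotation_db(fixture_db())
  rep <- mk_pairs(
    v_a = c("TRAV1", "TRAV1", "TRAV2", "TRAV2"),
    cdr3_a = c("CAVMDSSYKLIF", "CAVMDSSYKLIF", "CAGGGNKLTF", "CAGGGNKLTF"),
    v_b = c("TRBV5", "TRBV7", "TRBV5", "TRBV5"),
    cdr3_b = c("CASSLGETQYF", "CASSIRSSYEQYF", "CASSLGETQYF", "CASSLGETQYF")
  )
  out <- promiscuity_report(rep, db)
  a1 <- out[out$chain == "alpha" & out$gene == "TRAV1", ]
  # TRAV1 chain pairs with betas recognizing CMV-NLV and EBV-RAK: flagged
  expect_equal(a1$n_pairs, 2L)
  expect_true(a1$flagged)
  # TRAV2's single unique pairing is absent (appears once after dedup)
  expect_false("TRAV2" %in% out$gene[out$chain == "alpha"])
})
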