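test_that("clonotype table round-trips through TSV with validation reporting", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cells <- tiny_cells()
  readr::write_tsv(cells, path)
  got <- read_clonotype_table(path)
  expect_equal(nrow(got), 6L)
  expect_equal(got$cdr3_a, cells$cdr3_a)
  expect_equal(nrow(attr(got, "validation")), 0L)

  # a row with a non-amino-acid CDR3 is reported, and dropped in strict mode
  bad <- cells
  bad$cdr3_b[2] <- "CASBX1F"
  readr::write_tsv(bad, path)
  lenient <- read_clonotype_table(path)
  expect_equal(nrow(lenient), 6L)
  expect_equal(attr(lenient, "validation")$line, 3L)  # header is line 1
  strict <- read_clonotype_table(path, strict = TRUE)
  expect_equal(nrow(strict), 5L)

  # header-only file: empty result, no error
  readr::write_tsv(cells[0, ], path)
  expect_equal(nrow(read_clonotype_table(path)), 0L)

  # a dialect maps foreign column names; missing required column errors
  renamed <- dplyr::rename(cells, va_gene = v_a)
  readr::write_tsv(renamed, path)
  expect_error(read_clonotype_table(path), class = "tcrpair_config_error")
  got <- read_clonotype_table(path, dialect = c(v_a = "va_gene"))
  expect_equal(got$v_a, cells$v_a)
})

test_that("gene normalization strips alleles and applies aliases", {
  expect_equal(normalize_gene("TRBV20-1*01"), "TRBV20-1")
  expect_equal(normalize_gene(" TRAV1-2 "), "TRAV1-2")
  expect_equal(normalize_gene("TCRAV1", aliases = c(TCRAV1 = "TRAV1")), "TRAV1")
})

test_that("cell filtering applies the exclusion rules and reports reasons", {
  kept <- filter_cells(tiny_cells())
  expect_equal(nrow(kept), 4L)
  report <- attr(kept, "exclusions")
  expect_equal(report$n[report$reason == "no_lineage"], 1L)
  expect_equal(report$n[report$reason == "dual_receptor"], 1L)
  expect_true(all(kept$lineage %in% c("CD4", "CD8")))

  # clean input passes through with an empty report
  clean <- filter_cells(kept)
  expect_equal(nrow(clean), 4L)
  expect_equal(nrow(attr(clean, "exclusions")), 0L)

  # unpaired cells (a missing chain) are excluded with their own reason
  unp <- tiny_cells()
  unp$n_beta_chains[1] <- 0L
  rep2 <- attr(filter_cells(unp), "exclusions")
  expect_equal(rep2$n[rep2$reason == "unpaired"], 1L)
})

test_that("deduplication gives unique clonotypes per lineage at each scope", {
  cells <- filter_cells(tiny_cells())
  paired <- deduplicate(cells, "paired")
  # cells c1 and c2 share V+CDR3 on both chains (differ only in Jalpha):
  # one member under the V+CDR3 key; c6 is the same clonotype in CD8
  expect_equal(sum(paired$lineage == "CD4"), 1L)
  expect_equal(sum(paired$lineage == "CD8"), 2L)
  expect_equal(paired$clone_size[paired$lineage == "CD4" &
                                   paired$cdr3_a == "CAVMDSSYKLIF"], 2L)
  # the same clonotype appears once per lineage
  expect_equal(sum(grepl("CAVMDSSYKLIF", paired$key)), 2L)
  # with J in the key, c1 and c2 separate
  with_j <- deduplicate(cells, "paired", include_j = TRUE)
  expect_equal(sum(with_j$lineage == "CD4"), 2L)
  # dedup is idempotent: repeating the pipeline on kept cells changes nothing
  expect_equal(nrow(deduplicate(filter_cells(cells), "paired")), nrow(paired))
})

test_that("single-chain projections are consistent with the paired repertoire", {
  gen <- generate_repertoire(sim_config(n_cells = 2000, seed = 42))
  cells <- filter_cells(gen$cells)
  paired <- deduplicate(cells, "paired")
  for (chain in c("alpha", "beta")) {
    proj <- project_repertoire(paired, chain)
    direct <- deduplicate(cells, chain)
    expect_setequal(paste(proj$lineage, proj$key), paste(direct$lineage, direct$key))
  }
  a <- deduplicate(cells, "alpha"); b <- deduplicate(cells, "beta")
  expect_gte(nrow(paired), max(nrow(a), nrow(b)))
})

test_that("CDR3 primitives follow the charge and length conventions", {
  expect_equal(cdr3_charge("CASSLGETQYF"), -1L)
  expect_equal(cdr3_charge("CAKRDEF"), 0L)
  expect_equal(cdr3_charge("CASSF"), 0L)
  expect_equal(cdr3_charge("CHHHF"), 0L)  # histidine not counted
  expect_equal(cdr3_length("CASSF"), 5L)
  expect_equal(cdr3_length("CAVMDSSYKLIF"), 12L)
  expect_error(cdr3_length(""))
  expect_error(cdr3_charge("CASBX"))
  # charge is additive over concatenation
  set.seed(1)
  for (i in 1:20) {
    x <- paste(sample(c("A", "R", "K", "D", "E", "S"), 8, TRUE), collapse = "")
    y <- paste(sample(c("A", "R", "K", "D", "E", "S"), 5, TRUE), collapse = "")
    expect_equal(cdr3_charge(paste0(x, y)), cdr3_charge(x) + cdr3_charge(y))
  }
})

test_that("amino-acid frequencies pool residues and normalize", {
  rep1 <- deduplicate(filter_cells(tiny_cells()), "alpha")
  f <- aa_frequencies(rep1, "alpha")
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_length(f, 20L)
  # degenerate single-sequence repertoire
  one <- tibble::tibble(lineage = "CD4", subject = "S1",
                        v_a = "TRAV1", j_a = "TRAJ1", cdr3_a = "CCCC",
                        v_b = "TRBV1", j_b = "TRBJ1", cdr3_b = "CCCC",
                        n_alpha_chains = 1L, n_beta_chains = 1L, cell_id = "x")
  f1 <- aa_frequencies(deduplicate(one, "alpha"), "alpha")
  expect_equal(unname(f1["C"]), 1)
  # pooled counting over two sequences of different length
  two <- dplyr::bind_rows(one, dplyr::mutate(one, cdr3_a = "CA", cell_id = "y"))
  f2 <- aa_frequencies(deduplicate(two, "alpha"), "alpha")
  expect_equal(unname(f2["C"]), 5 / 6)
  expect_equal(unname(f2["A"]), 1 / 6)
})
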