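# Lineage classification from TCR features: fixed-length encoding (one-hot
# V/J genes, CDR3 length, CDR3 charge, 20 amino-acid usage frequencies per
# chain), gradient-boosted trees under stratified 5-fold cross-validation
# repeated 10 times, and comparison of alpha / beta / additive-ensemble /
# paired modes on fold-level AUCs.

#' Default boosted-tree configuration
#'
#' Hyperparameters are fixed for reproducibility: depth-6 trees, 200
#' boosting rounds, learning rate 0.3, single thread.
#'
#' @param max_depth,nrounds,eta Standard gradient-boosting controls.
#' @return Named list consumed by [cross_validate()].
#' @export
model_config <- function(max_depth = 6, nrounds = 200, eta = 0.3) {
  list(max_depth = max_depth, nrounds = nrounds, eta = eta)
}

# Per-chain numeric feature block: one-hot V and J + length + charge +
# 20 amino-acid frequencies.
encode_chain <- function(v, j, cdr3, v_universe, j_universe, prefix) {
  unknown_v <- setdiff(unique(v), v_universe)
  unknown_j <- setdiff(unique(j), j_universe)
  if (length(unknown_v) || length(unknown_j)) {
    abort_tcr(paste0("genes outside the configured universe: ",
                     paste(c(unknown_v, unknown_j), collapse = ", "),
                     " (universe from the dataset or encode()'s arguments)"))
  }
  one_hot <- function(x, levels, tag) {
    m <- matrix(0L, length(x), length(levels),
                dimnames = list(NULL, paste0(prefix, tag, levels)))
    m[cbind(seq_along(x), match(x, levels))] <- 1L
    m
  }
  counts <- t(vapply(strsplit(cdr3, "", fixed = TRUE), function(s) {
    tabulate(match(s, AA_ALPHABET), nbins = 20L)
  }, integer(20)))
  freqs <- counts / rowSums(counts)
  colnames(freqs) <- paste0(prefix, "aa_", AA_ALPHABET)
  cbind(
    one_hot(v, v_universe, "v_"),
    one_hot(j, j_universe, "j_"),
    matrix(cdr3_length(cdr3), ncol = 1, dimnames = list(NULL, paste0(prefix, "length"))),
    matrix(cdr3_charge(cdr3), ncol = 1, dimnames = list(NULL, paste0(prefix, "charge"))),
    freqs
  )
}

#' Encode clonotypes as a fixed-length numeric feature matrix
#'
#' @param dat Tibble with `v_a, j_a, cdr3_a, v_b, j_b, cdr3_b` columns
#'   (single-chain modes use only their chain's columns).
#' @param mode `"alpha"`, `"beta"`, or `"paired"` (concatenated blocks).
#' @param universe Optional list with `v_a, j_a, v_b, j_b` character vectors
#'   defining the gene universe; defaults to the genes observed in `dat`.
#' @return Numeric matrix, one row per clonotype; deterministic layout for
#'   a given universe.
#' @export
encode <- function(dat, mode = c("paired", "alpha", "beta"), universe = NULL) {
  mode <- match.arg(mode)
  universe <- universe %||% list(
    v_a = sort(unique(dat$v_a)), j_a = sort(unique(dat$j_a)),
    v_b = sort(unique(dat$v_b)), j_b = sort(unique(dat$j_b))
  )
  blocks <- list()
  if (mode %in% c("alpha", "paired")) {
    blocks$a <- encode_chain(dat$v_a, dat$j_a, dat$cdr3_a,
                             universe$v_a, universe$j_a, "a_")
  }
  if (mode %in% c("beta", "paired")) {
    blocks$b <- encode_chain(dat$v_b, dat$j_b, dat$cdr3_b,
                             universe$v_b, universe$j_b, "b_")
  }
  do.call(cbind, unname(blocks))
}

#' Prepare a labeled classification dataset
#'
#' Builds the training table from the unique paired clonotypes of filtered
#' cells, removing clonotypes found in both the CD4 and CD8 repertoires so
#' no label ambiguity remains, and attaching the lineage label. All
#' classifier modes draw on this one table (mode selects which feature
#' blocks are encoded), so rows and folds are identical across modes.
#'
#' @param cells Filtered cell tibble, or a paired-scope `tcr_repertoire`.
#' @return Tibble: `v_a, j_a, cdr3_a, v_b, j_b, cdr3_b, lineage, label`
#'   (`label` is 1 for CD4).
#' @export
prepare_dataset <- function(cells) {
  rep <- if (inherits(cells, "tcr_repertoire")) {
    if (rep_scope(cells) != "paired") abort_tcr("prepare_dataset() needs paired scope")
    cells
  } else {
    deduplicate(cells, scope = "paired", include_j = TRUE)
  }
  pkey <- paired_key(rep$v_a, rep$cdr3_a, rep$v_b, rep$cdr3_b)
  shared <- intersect(pkey[rep$lineage == "CD4"], pkey[rep$lineage == "CD8"])
  dat <- as_tibble(rep)[!(pkey %in% shared), ] |>
    distinct(.data$v_a, .data$j_a, .data$cdr3_a,
             .data$v_b, .data$j_b, .data$cdr3_b, .data$lineage) |>
    mutate(label = as.integer(.data$lineage == "CD4"))
  if (!all(c(0L, 1L) %in% dat$label)) {
    abort_tcr("a lineage class is empty after removing shared clonotypes")
  }
  dat
}

# Stratified fold assignment: within each class, a shuffled round-robin.
stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (cl in unique(label)) {
    idx <- which(label == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_xgb <- function(X, y, cfg) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                  eta = cfg$eta, nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = cfg$nrounds, verbose = 0
  )
}

#' Repeated stratified cross-validation of a lineage classifier
#'
#' Stratified 5-fold cross-validation repeated 10 times (distinct seeded
#' shuffles), fitting a gradient-boosted tree classifier per fold. The
#' `additive` mode fits separate alpha and beta models and soft-votes
#' (averages) their predicted CD4 probabilities. AUC is computed from the
#' predicted CD4 probability ranking; accuracy uses the 50% threshold.
#'
#' @param dataset Output of [prepare_dataset()].
#' @param mode `"alpha"`, `"beta"`, `"additive"`, or `"paired"`.
#' @param config Hyperparameters from [model_config()].
#' @param seed Integer seed; fold assignments are reproducible from it.
#' @param k Folds per repeat (default 5).
#' @param n_repeats Repeats (default 10).
#' @return A `tcr_cv` tibble with one row per repeat x fold (`auc`,
#'   `accuracy`, `n_test`), attributes `mode`, `seed`, and `roc` (pooled
#'   ROC points of the first repeat).
#' @export
cross_validate <- function(dataset, mode = c("paired", "alpha", "beta", "additive"),
                           config = model_config(), seed = 1L, k = 5L,
                           n_repeats = 10L) {
  mode <- match.arg(mode)
  if (nrow(dataset) < 100) abort_tcr("cross_validate() needs at least 100 clonotypes")
  if (length(unique(dataset$label)) < 2) abort_tcr("need both lineage classes")
  universe <- list(
    v_a = sort(unique(dataset$v_a)), j_a = sort(unique(dataset$j_a)),
    v_b = sort(unique(dataset$v_b)), j_b = sort(unique(dataset$j_b))
  )
  enc <- function(rows, m) encode(dataset[rows, ], mode = m, universe = universe)
  y <- dataset$label
  rows_out <- list()
  roc_scores <- NULL
  for (r in seq_len(n_repeats)) {
    set.seed(stage_seed(seed, paste0("cv_repeat_", r)))
    fold <- stratified_folds(y, k)
    rep_scores <- numeric(length(y))
    for (f in seq_len(k)) {
      test <- which(fold == f); train <- which(fold != f)
      prob <- if (mode == "additive") {
        ma <- fit_xgb(enc(train, "alpha"), y[train], config)
        mb <- fit_xgb(enc(train, "beta"), y[train], config)
        (predict(ma, xgboost::xgb.DMatrix(enc(test, "alpha"))) +
           predict(mb, xgboost::xgb.DMatrix(enc(test, "beta")))) / 2
      } else {
        m <- fit_xgb(enc(train, mode), y[train], config)
        predict(m, xgboost::xgb.DMatrix(enc(test, mode)))
      }
      rep_scores[test] <- prob
      rows_out[[length(rows_out) + 1L]] <- tibble(
        repeat_id = r, fold = f,
        auc = rank_auc(prob, y[test]),
        accuracy = mean((prob > 0.5) == (y[test] == 1L)),
        n_test = length(test)
      )
    }
    if (r == 1L) roc_scores <- rep_scores
  }
  out <- bind_rows(rows_out)
  thr <- sort(unique(c(0, roc_scores, 1)), decreasing = TRUE)
  roc <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(roc_scores[y == 1L] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(roc_scores[y == 0L] >= t), numeric(1))
  )
  structure(out, mode = mode, seed = seed, config = config, roc = roc,
            class = c("tcr_cv", class(out)))
}

#' Compare classifier modes on fold-level AUCs
#'
#' Pairwise two-sided rank-sum tests on the fold-level AUC distributions of
#' cross-validation results run on the same dataset and seeds.
#'
#' @param results Named list of `tcr_cv` results (names default to their
#'   modes).
#' @return Tibble of pairwise comparisons: mean +/- SD per mode and the
#'   rank-sum p-value.
#' @export
compare_modes <- function(results) {
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- map_chr(results, ~ attr(.x, "mode"))
  }
  ns <- map_int(results, nrow)
  if (length(unique(ns)) != 1) abort_tcr("compare_modes(): mismatched fold counts")
  combos <- utils::combn(names(results), 2, simplify = FALSE)
  map(combos, function(pr) {
    a <- results[[pr[1]]]$auc; b <- results[[pr[2]]]$auc
    pv <- if (isTRUE(all.equal(a, b))) 1 else {
      # exact U distribution at small n without ties, normal approximation
      # with tie correction otherwise (wilcox.test's own rule)
      suppressWarnings(wilcox.test(a, b)$p.value)
    }
    tibble(
      mode_1 = pr[1], mode_2 = pr[2],
      mean_auc_1 = mean(a), sd_auc_1 = sd(a),
      mean_auc_2 = mean(b), sd_auc_2 = sd(b),
      p_value = pv
    )
  }) |> bind_rows()
}
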