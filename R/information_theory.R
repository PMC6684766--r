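# Mutual information between TCR features and T cell lineage: plug-in
# estimator (bits), finite-sampling bias correction by subsampling
# extrapolation, and alpha-beta synergy decomposition
#   S = I(Xa, Xb; L) - I(Xa; L) - I(Xb; L).

mi_plugin_counts <- function(m) {
  n <- sum(m)
  if (n == 0) abort_tcr("mi_plugin(): empty table")
  p <- m / n
  ex <- outer(rowSums(p), colSums(p))
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ex[nz]))
}

#' Plug-in mutual information in bits
#'
#' Empirical mutual information of two categorical variables (feature and
#' lineage), `sum p(x,l) log2( p(x,l) / (p(x) p(l)) )`, with `0 log 0`
#' treated as 0. Accepts a contingency matrix of counts or two aligned
#' observation vectors.
#'
#' @param x Count matrix (features x lineages), or a vector of feature
#'   observations.
#' @param l Vector of lineage observations when `x` is a vector.
#' @return Mutual information in bits (non-negative).
#' @export
#' @examples
#' mi_plugin(matrix(c(5, 0, 0, 5), 2))  # 1 bit
mi_plugin <- function(x, l = NULL) {
  if (is.null(l)) {
    stopifnot(is.matrix(x) || is.table(x))
    return(mi_plugin_counts(as.matrix(x)))
  }
  if (length(x) != length(l)) abort_tcr("mi_plugin(): length mismatch")
  mi_plugin_counts(unclass(table(x, l)))
}

# Fast MI from integer codes (1..nx, 1..nl).
mi_codes <- function(xi, li, nx, nl) {
  counts <- tabulate((li - 1L) * nx + xi, nbins = nx * nl)
  mi_plugin_counts(matrix(counts, nx, nl))
}

# Subsample index draws shared across estimators (common random numbers):
# list over bootstrap replicates of lists over fractions.
draw_subsamples <- function(n, fractions, n_boot, seed) {
  set.seed(seed)
  sizes <- pmax(2L, round(fractions * n))
  map(seq_len(n_boot), function(b) {
    map(sizes, function(s) sample.int(n, s))
  })
}

#' Finite-sample-corrected mutual information
#'
#' The plug-in MI estimator is positively biased at finite sample size (to
#' first order by `(|X|-1)(|L|-1) / (2 N ln 2)`). This estimator subsamples
#' the data without replacement at several fractions, averages the plug-in
#' MI at each subsample size, fits a quadratic polynomial in `1/N`, and
#' reports the extrapolated infinite-sample intercept. The standard error
#' is the spread of per-replicate extrapolations.
#'
#' @param x,l Aligned categorical observation vectors (feature, lineage).
#' @param fractions Subsampling fractions in `(0, 1]`.
#' @param n_boot Subsample replicates per fraction.
#' @param seed Seed for the subsample draws.
#' @param indices Optional precomputed subsample draws
#'   (from `draw_subsamples`); used to share draws across estimates.
#' @return A `tcr_info` list: `mi_plugin`, `mi_corrected`, `se`, `n`, and
#'   `diagnostics` (fit record, per-replicate intercepts, degeneracy flag).
#' @export
mi_corrected <- function(x, l, fractions = c(0.5, 0.625, 0.75, 0.875, 1),
                         n_boot = 50, seed = 1L, indices = NULL) {
  if (length(x) != length(l)) abort_tcr("mi_corrected(): length mismatch")
  n <- length(x)
  if (n < 100) abort_tcr("mi_corrected() needs at least 100 observations")
  if (any(fractions <= 0 | fractions > 1)) abort_tcr("fractions must lie in (0, 1]")
  if (min(round(fractions * n)) < 10) abort_tcr("smallest subsampling fraction leaves too few samples")
  xf <- factor(x); lf <- factor(l)
  xi <- as.integer(xf); li <- as.integer(lf)
  nx <- nlevels(xf); nl <- nlevels(lf)
  plugin <- mi_codes(xi, li, nx, nl)
  if (is.null(indices)) indices <- draw_subsamples(n, fractions, n_boot, seed)
  n_boot <- length(indices)
  sizes <- lengths(indices[[1]])
  mi_mat <- vapply(indices, function(draws) {
    vapply(draws, function(idx) mi_codes(xi[idx], li[idx], nx, nl), numeric(1))
  }, numeric(length(fractions)))
  mi_mat <- matrix(mi_mat, nrow = length(fractions))  # fractions x n_boot
  if (length(fractions) == 1L) {
    return(structure(list(
      mi_plugin = plugin, mi_corrected = mean(mi_mat), se = 0, n = n,
      diagnostics = list(degenerate = TRUE, fractions = fractions,
                         sizes = sizes, intercepts = rowMeans(mi_mat))
    ), class = "tcr_info"))
  }
  degree <- min(2L, length(fractions) - 1L)
  inv_n <- 1 / sizes
  X <- stats::poly(inv_n, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  fit <- qr(X)
  intercepts <- apply(mi_mat, 2, function(y) qr.coef(fit, y)[1])
  mean_curve <- rowMeans(mi_mat)
  mean_fit <- qr.coef(fit, mean_curve)
  residuals <- mean_curve - as.vector(X %*% mean_fit)
  structure(list(
    mi_plugin = plugin,
    mi_corrected = mean(intercepts),
    se = if (n_boot > 1) sd(intercepts) else NA_real_,
    n = n,
    diagnostics = list(degenerate = FALSE, fractions = fractions, sizes = sizes,
                       degree = degree, mean_curve = mean_curve,
                       residuals = residuals, intercepts = intercepts)
  ), class = "tcr_info")
}

#' @export
print.tcr_info <- function(x, ...) {
  cat(sprintf("<tcr_info> n=%d  plug-in=%.4f bits  corrected=%.4f bits (se %.4f)\n",
              x$n, x$mi_plugin, x$mi_corrected, x$se))
  invisible(x)
}

#' Alpha-beta information synergy
#'
#' Synergy of two features with respect to lineage:
#' `S = I(Xa, Xb; L) - I(Xa; L) - I(Xb; L)`. Positive values mean the pair
#' carries information beyond its parts; negative values indicate
#' redundancy. With the corrected estimator, all three terms use identical
#' subsample draws so that the difference is not dominated by independent
#' subsampling noise.
#'
#' @param xa,xb,l Aligned observation vectors (alpha feature, beta feature,
#'   lineage).
#' @param estimator `"plugin"` or `"corrected"`.
#' @param ... Passed to [mi_corrected()] (`fractions`, `n_boot`, `seed`).
#' @return A `tcr_synergy` list: `s`, `se`, and `components` (named list of
#'   `tcr_info` for joint, alpha, beta).
#' @export
synergy <- function(xa, xb, l, estimator = c("plugin", "corrected"), ...) {
  estimator <- match.arg(estimator)
  if (length(xa) != length(l) || length(xb) != length(l)) {
    abort_tcr("synergy(): length mismatch")
  }
  joint <- paste(xa, xb, sep = "\r")
  if (estimator == "plugin") {
    comp <- list(
      joint = list(mi_plugin = mi_plugin(joint, l), mi_corrected = mi_plugin(joint, l),
                   se = 0, n = length(l)),
      alpha = list(mi_plugin = mi_plugin(xa, l), mi_corrected = mi_plugin(xa, l),
                   se = 0, n = length(l)),
      beta = list(mi_plugin = mi_plugin(xb, l), mi_corrected = mi_plugin(xb, l),
                  se = 0, n = length(l))
    )
    comp <- map(comp, ~ structure(.x, class = "tcr_info"))
    s <- comp$joint$mi_corrected - comp$alpha$mi_corrected - comp$beta$mi_corrected
    return(structure(list(s = s, se = 0, components = comp, estimator = estimator),
                     class = "tcr_synergy"))
  }
  dots <- list(...)
  fractions <- dots$fractions %||% c(0.5, 0.625, 0.75, 0.875, 1)
  n_boot <- dots$n_boot %||% 50
  seed <- dots$seed %||% 1L
  idx <- draw_subsamples(length(l), fractions, n_boot, seed)
  comp <- list(
    joint = mi_corrected(joint, l, fractions = fractions, indices = idx),
    alpha = mi_corrected(xa, l, fractions = fractions, indices = idx),
    beta = mi_corrected(xb, l, fractions = fractions, indices = idx)
  )
  s <- comp$joint$mi_corrected - comp$alpha$mi_corrected - comp$beta$mi_corrected
  se <- tryCatch({
    di <- comp$joint$diagnostics$intercepts - comp$alpha$diagnostics$intercepts -
      comp$beta$diagnostics$intercepts
    if (length(di) > 1) sd(di) else NA_real_
  }, error = function(e) NA_real_)
  structure(list(s = s, se = se, components = comp, estimator = estimator),
            class = "tcr_synergy")
}

#' @export
print.tcr_synergy <- function(x, ...) {
  cat(sprintf("<tcr_synergy> S = %.4f bits (se %.4f, %s estimator)\n",
              x$s, x$se, x$estimator))
  cat(sprintf("  joint %.4f | alpha %.4f | beta %.4f bits\n",
              x$components$joint$mi_corrected, x$components$alpha$mi_corrected,
              x$components$beta$mi_corrected))
  invisible(x)
}

#' Information profile across TCR feature types
#'
#' For each feature type (V gene, J gene, CDR3 length, CDR3 charge),
#' estimates the information about lineage carried by the alpha chain, the
#' beta chain, their sum (the conditional-independence expectation), the
#' joint alpha-beta feature, and the synergy. Works from the unique paired
#' clonotype set, from which both single-chain views are projected, so all
#' estimates share one sample size.
#'
#' @param cells Filtered cell tibble.
#' @param feature_types Subset of `c("v_gene", "j_gene", "length", "charge")`.
#' @param estimator `"corrected"` (default) or `"plugin"`.
#' @param ... Passed to [mi_corrected()].
#' @return A `tcr_info_profile` tibble: one row per feature type with
#'   `mi_alpha, mi_beta, mi_sum, mi_paired, synergy` and standard errors.
#' @export
feature_info_profile <- function(cells,
                                 feature_types = c("v_gene", "j_gene", "length", "charge"),
                                 estimator = c("corrected", "plugin"), ...) {
  estimator <- match.arg(estimator)
  feature_types <- match.arg(feature_types, several.ok = TRUE)
  rep <- deduplicate(cells, scope = "paired", include_j = TRUE)
  l <- rep$lineage
  col_of <- function(ft, chain) {
    switch(ft,
      v_gene = if (chain == "a") rep$v_a else rep$v_b,
      j_gene = if (chain == "a") rep$j_a else rep$j_b,
      length = as.character(cdr3_length(if (chain == "a") rep$cdr3_a else rep$cdr3_b)),
      charge = as.character(cdr3_charge(if (chain == "a") rep$cdr3_a else rep$cdr3_b))
    )
  }
  rows <- map(feature_types, function(ft) {
    syn <- synergy(col_of(ft, "a"), col_of(ft, "b"), l, estimator = estimator, ...)
    tibble(
      feature_type = ft, n = length(l),
      mi_alpha = syn$components$alpha$mi_corrected,
      se_alpha = syn$components$alpha$se,
      mi_beta = syn$components$beta$mi_corrected,
      se_beta = syn$components$beta$se,
      mi_sum = syn$components$alpha$mi_corrected + syn$components$beta$mi_corrected,
      mi_paired = syn$components$joint$mi_corrected,
      se_paired = syn$components$joint$se,
      synergy = syn$s, se_synergy = syn$se
    )
  })
  out <- bind_rows(rows)
  structure(out, estimator = estimator,
            class = c("tcr_info_profile", class(out)))
}
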