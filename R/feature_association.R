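# CD4:CD8 odds-ratio scans over single-chain and paired TCR features, with
# exact two-sided p-values, Woolf confidence intervals, and multiple-testing
# control (Bonferroni for single-chain scans, q-values for paired scans).

SINGLE_FEATURES <- c("v_gene", "j_gene", "charge", "length")
PAIR_FEATURES <- c("v_pair", "j_pair", "charge_pair", "length_pair")

# Two-sided exact p for a 2x2 table with fixed margins: enumerate the
# hypergeometric support and sum the probabilities of all tables at most as
# probable as the observed one (with the customary 1 + 1e-7 tie slack).
hypergeom_p2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(c1, r1)
  dens <- stats::dhyper(support, r1, r2, c1)
  p_obs <- dens[support == a]
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio with exact test for one 2x2 feature table
#'
#' Counts `a, b, c, d` are: CD4 clonotypes with / without the feature, CD8
#' clonotypes with / without it. The odds ratio is the sample odds ratio
#' `(a d) / (b c)`; the p-value is the exact two-sided hypergeometric tail
#' probability; the 95% CI is a normal approximation on the log odds ratio
#' (Woolf), with a Haldane-Anscombe 0.5 added to every cell when any cell
#' is zero. The OR is `Inf` when `b c = 0` and `a d > 0`.
#'
#' @param a,b,c,d Non-negative integer counts with `a + b > 0`, `c + d > 0`.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `a, b, c, d, odds_ratio, ci_low, ci_high, p`.
#' @export
odds_ratio_test <- function(a, b, c, d, conf = 0.95) {
  if (a + b == 0 || c + d == 0) abort_tcr("odds_ratio_test(): empty lineage margin")
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  z <- qnorm(1 - (1 - conf) / 2)
  h <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  lo <- exp(log(((a + h) * (d + h)) / ((b + h) * (c + h))) -
              z * sqrt(1 / (a + h) + 1 / (b + h) + 1 / (c + h) + 1 / (d + h)))
  hi <- exp(log(((a + h) * (d + h)) / ((b + h) * (c + h))) +
              z * sqrt(1 / (a + h) + 1 / (b + h) + 1 / (c + h) + 1 / (d + h)))
  tibble(a = a, b = b, c = c, d = d, odds_ratio = or,
         ci_low = lo, ci_high = hi, p = hypergeom_p2(a, b, c, d))
}

# Pool sparse integer feature values (total count < min_count) into the
# distribution's tails, labelling merged bins "<=k" / ">=k".
pool_integer_tails <- function(values, min_count = 10L) {
  tab <- table(values)
  vals <- as.integer(names(tab))
  o <- order(vals)
  vals <- vals[o]; cnt <- as.integer(tab)[o]
  if (length(vals) <= 2L) return(setNames(as.character(vals), as.character(vals)))
  lo_idx <- 1L
  while (lo_idx < length(vals) && sum(cnt[seq_len(lo_idx)]) < min_count) lo_idx <- lo_idx + 1L
  hi_idx <- length(vals)
  while (hi_idx > lo_idx && sum(cnt[hi_idx:length(vals)]) < min_count) hi_idx <- hi_idx - 1L
  labels <- as.character(vals)
  if (lo_idx > 1L) labels[seq_len(lo_idx)] <- paste0("<=", vals[lo_idx])
  if (hi_idx < length(vals)) labels[hi_idx:length(vals)] <- paste0(">=", vals[hi_idx])
  setNames(labels, as.character(vals))
}

# Feature value per clonotype for a repertoire at the appropriate scope.
feature_values <- function(rep, feature_type) {
  scope <- rep_scope(rep)
  single <- feature_type %in% SINGLE_FEATURES
  if (single && scope == "paired") {
    abort_tcr(paste0("feature '", feature_type, "' needs a single-chain repertoire"))
  }
  if (!single && scope != "paired") {
    abort_tcr(paste0("feature '", feature_type, "' needs a paired repertoire"))
  }
  if (feature_type %in% c("j_gene", "j_pair") && !isTRUE(attr(rep, "include_j"))) {
    abort_tcr("J-segment features require deduplicate(..., include_j = TRUE)")
  }
  switch(feature_type,
    v_gene = if (scope == "alpha") rep$v_a else rep$v_b,
    j_gene = if (scope == "alpha") rep$j_a else rep$j_b,
    charge = as.character(cdr3_charge(if (scope == "alpha") rep$cdr3_a else rep$cdr3_b)),
    length = as.character(cdr3_length(if (scope == "alpha") rep$cdr3_a else rep$cdr3_b)),
    v_pair = paste(rep$v_a, rep$v_b, sep = ":"),
    j_pair = paste(rep$j_a, rep$j_b, sep = ":"),
    charge_pair = paste(cdr3_charge(rep$cdr3_a), cdr3_charge(rep$cdr3_b), sep = ":"),
    length_pair = paste(cdr3_length(rep$cdr3_a), cdr3_length(rep$cdr3_b), sep = ":"),
    abort_tcr(paste0("unknown feature type: ", feature_type))
  )
}

#' Enumerate 2x2 feature counts for a CD4/CD8 repertoire pair
#'
#' One row per observed feature value: CD4 clonotypes with/without the
#' feature and CD8 clonotypes with/without it. Each unique clonotype
#' contributes once. Charge features pool values with total count below 10
#' into the distribution's tails (per chain for charge pairs).
#'
#' @param rep A `tcr_repertoire` with CD4 and CD8 rows (or the CD4 half).
#' @param feature_type One of `v_gene, j_gene, charge, length` (single-chain
#'   scope) or `v_pair, j_pair, charge_pair, length_pair` (paired scope).
#' @param cd8 Optional CD8 repertoire when `rep` holds CD4 only.
#' @return Tibble: `feature, a, b, c, d`.
#' @export
enumerate_features <- function(rep, feature_type, cd8 = NULL) {
  if (!is.null(cd8)) {
    if (!identical(rep_scope(rep), rep_scope(cd8))) {
      abort_tcr("enumerate_features(): repertoires have different scopes")
    }
    rep <- structure(bind_rows(as_tibble(rep), as_tibble(cd8)),
                     scope = rep_scope(rep), include_j = attr(rep, "include_j"),
                     class = c("tcr_repertoire", "tbl_df", "tbl", "data.frame"))
  }
  vals <- feature_values(rep, feature_type)
  if (feature_type == "charge") {
    vals <- unname(pool_integer_tails(as.integer(vals))[vals])
  } else if (feature_type == "charge_pair") {
    parts <- str_split(vals, ":", simplify = TRUE)
    map_a <- pool_integer_tails(as.integer(parts[, 1]))
    map_b <- pool_integer_tails(as.integer(parts[, 2]))
    vals <- paste(map_a[parts[, 1]], map_b[parts[, 2]], sep = ":")
  }
  lin <- rep$lineage
  n4 <- sum(lin == "CD4"); n8 <- sum(lin == "CD8")
  if (n4 == 0 || n8 == 0) abort_tcr("both CD4 and CD8 clonotypes are required")
  tab4 <- table(factor(vals[lin == "CD4"], levels = sort(unique(vals))))
  tab8 <- table(factor(vals[lin == "CD8"], levels = sort(unique(vals))))
  tibble(
    feature = names(tab4),
    a = as.integer(tab4), b = n4 - as.integer(tab4),
    c = as.integer(tab8), d = n8 - as.integer(tab8)
  )
}

# Storey q-values: pi0 estimated on a lambda grid with cubic-spline
# smoothing, falling back to Benjamini-Hochberg for small or unstable
# families.
storey_qvalue <- function(p, lambda = seq(0, 0.95, by = 0.05)) {
  m <- length(p)
  fallback <- function() p.adjust(p, method = "BH")
  if (m < 100) return(fallback())
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    min(1, max(predict(fit, x = max(lambda))$y, 0))
  }, error = function(e) NA_real_)
  if (is.na(pi0) || pi0 <= 0) return(fallback())
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[order(o)]
}

#' Odds-ratio association scan over a feature family
#'
#' Computes the CD4:CD8 odds ratio, exact p-value, and CI for every observed
#' feature value, then applies multiple-testing control: Bonferroni across
#' the scan for single-chain features, q-values for paired features (whose
#' families are much larger). Significance is called at adjusted < 0.05.
#'
#' @inheritParams enumerate_features
#' @param conf CI level.
#' @param sig_level Significance threshold on the adjusted value.
#' @return A `tcr_scan` tibble: `feature, a, b, c, d, odds_ratio, ci_low,
#'   ci_high, p, adjusted, significant`, with attributes `feature_type` and
#'   `adjust_method`.
#' @export
association_scan <- function(rep, feature_type, cd8 = NULL, conf = 0.95,
                             sig_level = 0.05) {
  counts <- enumerate_features(rep, feature_type, cd8)
  res <- pmap(counts[c("a", "b", "c", "d")],
              function(a, b, c, d) odds_ratio_test(a, b, c, d, conf = conf))
  out <- bind_rows(res)
  out$feature <- counts$feature
  method <- if (feature_type %in% SINGLE_FEATURES) "bonferroni" else "qvalue"
  out$adjusted <- if (method == "bonferroni") {
    p.adjust(out$p, method = "bonferroni")
  } else {
    storey_qvalue(out$p)
  }
  out$significant <- out$adjusted < sig_level
  out <- out[c("feature", "a", "b", "c", "d", "odds_ratio",
               "ci_low", "ci_high", "p", "adjusted", "significant")]
  structure(out, feature_type = feature_type, adjust_method = method,
            class = c("tcr_scan", class(out)))
}

#' Per-amino-acid CD4/CD8 usage-ratio test
#'
#' For each of the 20 amino acids, the CD4/CD8 CDR3 usage-frequency ratio is
#' computed per subject, and a one-sample t-test of the log-ratio against 0
#' is Bonferroni-corrected over the 20 tests. Subjects in which an amino
#' acid is absent from the CD8 CDR3s are excluded from that amino acid's
#' test with a warning.
#'
#' @param cells Filtered cell tibble with at least two subjects.
#' @param chain `"alpha"` or `"beta"`.
#' @return Tibble: `aa, n_subjects, mean_ratio, p, adjusted, zero_variance`.
#' @export
aa_usage_ratio_test <- function(cells, chain = c("alpha", "beta")) {
  chain <- match.arg(chain)
  subjects <- unique(cells$subject)
  if (length(subjects) < 2) abort_tcr("aa_usage_ratio_test() needs >= 2 subjects")
  freq_of <- function(sub, lin) {
    sub_cells <- cells[cells$subject == sub & cells$lineage == lin, ]
    if (!nrow(sub_cells)) return(rep(NA_real_, 20) |> setNames(AA_ALPHABET))
    aa_frequencies(deduplicate(sub_cells, scope = chain), chain)
  }
  ratios <- map(subjects, function(s) freq_of(s, "CD4") / freq_of(s, "CD8"))
  mat <- do.call(rbind, ratios)  # subjects x 20
  dropped <- FALSE
  res <- map(AA_ALPHABET, function(aa) {
    r <- mat[, aa]
    bad <- !is.finite(r) | r <= 0
    if (any(bad)) dropped <<- TRUE
    r <- r[!bad]
    if (length(r) < 2) {
      return(tibble(aa = aa, n_subjects = length(r), mean_ratio = mean(r),
                    p = NA_real_, zero_variance = FALSE))
    }
    lr <- log(r)
    if (sd(lr) == 0) {
      tibble(aa = aa, n_subjects = length(r), mean_ratio = mean(r),
             p = if (all(lr == 0)) 1 else 0, zero_variance = TRUE)
    } else {
      tibble(aa = aa, n_subjects = length(r), mean_ratio = mean(r),
             p = t.test(lr, mu = 0)$p.value, zero_variance = FALSE)
    }
  }) |> bind_rows()
  if (dropped) {
    warn("some subject/amino-acid ratios were undefined (zero CD8 usage) and were excluded")
  }
  res$adjusted <- pmin(res$p * 20, 1)
  res
}

#' Compare association strength of paired vs single-chain features
#'
#' Restricts both scans to significant features biased toward the requested
#' lineage (OR > 1 for CD4, OR < 1 for CD8; infinite ORs excluded) and
#' compares the |log OR| distributions with a two-sided rank-sum test.
#'
#' @param single_results,paired_results `tcr_scan` tibbles.
#' @param direction `"CD4"` or `"CD8"`.
#' @return One-row tibble: group medians, IQRs, n, and the rank-sum p-value
#'   (`NA` with `applicable = FALSE` when either group is empty).
#' @export
strength_comparison <- function(single_results, paired_results,
                                direction = c("CD4", "CD8")) {
  direction <- match.arg(direction)
  pick <- function(res) {
    dir_ok <- if (direction == "CD4") res$odds_ratio > 1 else res$odds_ratio < 1
    keep <- res$significant & is.finite(res$odds_ratio) & res$odds_ratio > 0 & dir_ok
    abs(log(res$odds_ratio[keep]))
  }
  s <- pick(single_results); p <- pick(paired_results)
  if (!length(s) || !length(p)) {
    return(tibble(direction = direction, n_single = length(s), n_paired = length(p),
                  median_single = NA_real_, median_paired = NA_real_,
                  iqr_single = NA_real_, iqr_paired = NA_real_,
                  p_value = NA_real_, applicable = FALSE))
  }
  pv <- suppressWarnings(wilcox.test(p, s, exact = FALSE, correct = TRUE)$p.value)
  tibble(direction = direction, n_single = length(s), n_paired = length(p),
         median_single = median(s), median_paired = median(p),
         iqr_single = stats::IQR(s), iqr_paired = stats::IQR(p),
         p_value = pv, applicable = TRUE)
}
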