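# CD4/CD8 repertoire overlap: Jaccard index, pooled and per-subject
# sharing, shared-vs-exclusive CDR3 length comparison, and a pluggable
# generation-probability hook.

#' Jaccard index of two clonotype sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b Character vectors of clonotype keys (or any set members).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) abort_tcr("jaccard() of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Summarise CD4/CD8 repertoire overlap
#'
#' Pooled and per-subject sharing between the CD4 and CD8 repertoires of a
#' deduplicated clonotype table at one scope. `overlap_percent` is the
#' shared count as a percentage of the union of unique clonotypes.
#'
#' @param rep A `tcr_repertoire` (from [deduplicate()]) containing both
#'   CD4 and CD8 rows, or two repertoires `cd4` and `cd8` of equal scope.
#' @param cd8 Optional second repertoire when `rep` holds CD4 only.
#' @return A `tcr_overlap` list: `scope`, `jaccard`, `overlap_percent`,
#'   `n_shared`, `n_cd4_only`, `n_cd8_only`, and `per_subject` (tibble of
#'   subject-level Jaccard indices).
#' @export
overlap_summary <- function(rep, cd8 = NULL) {
  if (!is.null(cd8)) {
    if (!identical(rep_scope(rep), rep_scope(cd8))) {
      abort_tcr("overlap_summary(): repertoires have different scopes")
    }
    rep <- structure(bind_rows(as_tibble(rep), as_tibble(cd8)),
                     scope = rep_scope(rep),
                     class = c("tcr_repertoire", class(as_tibble(rep))))
  }
  k4 <- rep$key[rep$lineage == "CD4"]
  k8 <- rep$key[rep$lineage == "CD8"]
  n_shared <- length(intersect(k4, k8))
  n4 <- length(k4) - n_shared
  n8 <- length(k8) - n_shared
  per_subject <- rep |>
    as_tibble() |>
    tidyr::unnest_longer("subjects", values_to = "subject") |>
    group_by(.data$subject) |>
    summarise(
      jaccard = {
        s4 <- .data$key[.data$lineage == "CD4"]
        s8 <- .data$key[.data$lineage == "CD8"]
        if (length(s4) + length(s8) == 0) NA_real_ else jaccard(s4, s8)
      },
      n_cd4 = sum(.data$lineage == "CD4"),
      n_cd8 = sum(.data$lineage == "CD8"),
      .groups = "drop"
    )
  structure(list(
    scope = rep_scope(rep),
    jaccard = n_shared / (n_shared + n4 + n8),
    overlap_percent = 100 * n_shared / (n_shared + n4 + n8),
    n_shared = n_shared, n_cd4_only = n4, n_cd8_only = n8,
    per_subject = per_subject
  ), class = "tcr_overlap")
}

#' @export
print.tcr_overlap <- function(x, ...) {
  cat(sprintf("<tcr_overlap> scope=%s  shared=%d  CD4-only=%d  CD8-only=%d\n",
              x$scope, x$n_shared, x$n_cd4_only, x$n_cd8_only))
  cat(sprintf("  Jaccard = %.4g   overlap = %.3g%% of union\n",
              x$jaccard, x$overlap_percent))
  invisible(x)
}

#' Gap between paired overlap and the single-chain product
#'
#' If the alpha and beta chains were shared independently, the paired
#' overlap fraction would equal the product of the single-chain overlap
#' fractions. Returns the signed gap `paired - alpha * beta` as a
#' diagnostic of that independence approximation.
#'
#' @param alpha_ov,beta_ov,paired_ov Overlap fractions in `[0, 1]`.
#' @return Signed gap (number).
#' @export
product_rule_gap <- function(alpha_ov, beta_ov, paired_ov) {
  stopifnot(alpha_ov >= 0, alpha_ov <= 1, beta_ov >= 0, beta_ov <= 1,
            paired_ov >= 0, paired_ov <= 1)
  paired_ov - alpha_ov * beta_ov
}

#' Compare CDR3 lengths of shared vs lineage-exclusive clonotypes
#'
#' Splits a repertoire into clonotypes shared between CD4 and CD8 and those
#' exclusive to one lineage, and compares mean CDR3 lengths (for paired
#' scope, the sum of both chains' lengths) with percentile-bootstrap 99%
#' confidence intervals and a two-sided rank-sum test.
#'
#' @param rep A `tcr_repertoire` with CD4 and CD8 rows.
#' @param n_boot Bootstrap resamples for the CI (default 10000).
#' @param conf CI level (default 0.99).
#' @param seed Seed for the bootstrap.
#' @return A tibble with one row per set (`shared`, `exclusive`): n, mean
#'   length, CI bounds, plus attributes `p_value` (rank-sum) and
#'   `applicable`/`degenerate` flags.
#' @export
shared_vs_exclusive_lengths <- function(rep, n_boot = 10000, conf = 0.99,
                                        seed = 1L) {
  scope <- rep_scope(rep)
  lens <- switch(scope,
    alpha = cdr3_length(rep$cdr3_a),
    beta = cdr3_length(rep$cdr3_b),
    paired = cdr3_length(rep$cdr3_a) + cdr3_length(rep$cdr3_b)
  )
  k4 <- rep$key[rep$lineage == "CD4"]
  k8 <- rep$key[rep$lineage == "CD8"]
  shared_keys <- intersect(k4, k8)
  is_shared <- rep$key %in% shared_keys
  # one length per unique clonotype (shared clonotypes appear once per
  # lineage with identical sequence; collapse to one)
  dd <- tibble(key = rep$key, len = lens, shared = is_shared) |> distinct()
  boot_ci <- function(x) {
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    means <- map_dbl(seq_len(n_boot), function(i) mean(sample(x, replace = TRUE)))
    unname(quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  set.seed(seed)
  sh <- dd$len[dd$shared]
  ex <- dd$len[!dd$shared]
  if (!length(sh)) {
    out <- tibble(set = c("shared", "exclusive"), n = c(0L, length(ex)),
                  mean_length = c(NA_real_, mean(ex)),
                  ci_low = NA_real_, ci_high = NA_real_)
    attr(out, "applicable") <- FALSE
    return(out)
  }
  ci_sh <- boot_ci(sh); ci_ex <- boot_ci(ex)
  p <- if (length(ex)) {
    suppressWarnings(wilcox.test(sh, ex, exact = FALSE, correct = TRUE)$p.value)
  } else NA_real_
  out <- tibble(
    set = c("shared", "exclusive"), n = c(length(sh), length(ex)),
    mean_length = c(mean(sh), mean(ex)),
    ci_low = c(ci_sh[1], ci_ex[1]), ci_high = c(ci_sh[2], ci_ex[2])
  )
  attr(out, "applicable") <- TRUE
  attr(out, "degenerate") <- length(sh) < 2 || length(ex) < 2
  attr(out, "p_value") <- p
  out
}

#' Generation-probability hook
#'
#' Delegates per-chain CDR3 generation-probability computation to a
#' caller-supplied engine (e.g. an external generative-model wrapper); for
#' paired clonotypes the probability is the product of the chain
#' probabilities, assuming independent alpha and beta generation. No engine
#' ships with the package.
#'
#' @param rep A `tcr_repertoire`.
#' @param engine Function `(v_gene, cdr3_aa, chain) -> probability`,
#'   vectorized or scalar.
#' @return The repertoire tibble with a `pgen` column.
#' @export
pgen_hook <- function(rep, engine = NULL) {
  if (is.null(engine)) {
    abort_tcr(paste0("generation probabilities are disabled: no engine configured; ",
                     "supply engine = function(v_gene, cdr3_aa, chain) ..."),
              class = "tcrpair_disabled_feature")
  }
  call_engine <- function(v, cdr3, chain) {
    out <- tryCatch(mapply(engine, v, cdr3, MoreArgs = list(chain = chain)),
                    error = function(e) {
                      abort_tcr(paste0("pgen engine failed on ", chain, " chain ",
                                       v[1], " ", cdr3[1], ": ", conditionMessage(e)))
                    })
    as.numeric(out)
  }
  scope <- rep_scope(rep)
  pgen <- switch(scope,
    alpha = call_engine(rep$v_a, rep$cdr3_a, "alpha"),
    beta = call_engine(rep$v_b, rep$cdr3_b, "beta"),
    paired = call_engine(rep$v_a, rep$cdr3_a, "alpha") *
      call_engine(rep$v_b, rep$cdr3_b, "beta")
  )
  mutate(as_tibble(rep), pgen = pgen)
}
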