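# broom-style tidiers for fitted/computed result objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an odds-ratio scan
#'
#' @param x A `tcr_scan`.
#' @param ... Ignored.
#' @return A tibble with one row per feature (estimate on the log-OR scale
#'   alongside the raw columns).
#' @export
tidy.tcr_scan <- function(x, ...) {
  as_tibble(x) |>
    mutate(term = .data$feature, estimate = log(.data$odds_ratio)) |>
    select("term", "estimate", "odds_ratio", "ci_low", "ci_high",
           "p", "adjusted", "significant", "a", "b", "c", "d")
}

#' @export
glance.tcr_scan <- function(x, ...) {
  tibble(
    feature_type = attr(x, "feature_type"),
    adjust_method = attr(x, "adjust_method"),
    n_features = nrow(x),
    n_significant = sum(x$significant)
  )
}

#' Tidy cross-validation fold metrics
#'
#' @param x A `tcr_cv`.
#' @param ... Ignored.
#' @return Fold-level tibble with the mode attached.
#' @export
tidy.tcr_cv <- function(x, ...) {
  mutate(as_tibble(x), mode = attr(x, "mode"), .before = 1)
}

#' @export
glance.tcr_cv <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    n_folds = nrow(x),
    mean_auc = mean(x$auc), sd_auc = sd(x$auc),
    mean_accuracy = mean(x$accuracy), sd_accuracy = sd(x$accuracy)
  )
}

#' Tidy an overlap summary
#'
#' @param x A `tcr_overlap`.
#' @param ... Ignored.
#' @return Per-subject tibble with pooled values attached as columns.
#' @export
tidy.tcr_overlap <- function(x, ...) {
  mutate(x$per_subject, scope = x$scope, .before = 1)
}

#' @export
glance.tcr_overlap <- function(x, ...) {
  tibble(scope = x$scope, jaccard = x$jaccard,
         overlap_percent = x$overlap_percent, n_shared = x$n_shared,
         n_cd4_only = x$n_cd4_only, n_cd8_only = x$n_cd8_only)
}

#' Tidy a mutual-information estimate
#'
#' @param x A `tcr_info`.
#' @param ... Ignored.
#' @return One-row tibble.
#' @export
tidy.tcr_info <- function(x, ...) {
  tibble(mi_plugin = x$mi_plugin, mi_corrected = x$mi_corrected,
         se = x$se, n = x$n)
}

#' Tidy a synergy decomposition
#'
#' @param x A `tcr_synergy`.
#' @param ... Ignored.
#' @return Tibble with one row per component plus the synergy row.
#' @export
tidy.tcr_synergy <- function(x, ...) {
  bind_rows(
    imap(x$components, ~ mutate(tidy.tcr_info(.x), term = .y, .before = 1)),
    tibble(term = "synergy", mi_plugin = NA_real_, mi_corrected = x$s,
           se = x$se, n = x$components$joint$n)
  )
}
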