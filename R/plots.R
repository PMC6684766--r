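# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_errorbar
#'   geom_errorbarh geom_hline geom_vline geom_line geom_tile geom_boxplot
#'   geom_abline scale_y_log10 scale_x_log10 labs theme_minimal autoplot
#'   facet_wrap position_dodge scale_fill_gradient coord_equal
NULL

#' Plot an odds-ratio scan
#'
#' Forest-style plot of odds ratios with confidence intervals, significant
#' features highlighted; infinite ORs are omitted.
#'
#' @param object A `tcr_scan` from [association_scan()].
#' @param top Show only the `top` features by smallest p (default 40).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.tcr_scan <- function(object, top = 40, ...) {
  dat <- as_tibble(object) |>
    filter(is.finite(.data$odds_ratio), .data$odds_ratio > 0) |>
    arrange(.data$p)
  dat <- dat[seq_len(min(top, nrow(dat))), ]
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot(dat, aes(x = .data$odds_ratio, y = .data$feature,
                  colour = .data$significant)) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point() +
    scale_x_log10() +
    labs(x = "CD4:CD8 odds ratio (log scale)", y = NULL,
         colour = "significant",
         title = paste0("Lineage association: ", attr(object, "feature_type"))) +
    theme_minimal()
}

#' Plot an information profile
#'
#' Grouped bars of corrected mutual information per feature type for the
#' alpha chain, beta chain, their sum, and the joint pair; the gap between
#' the paired and summed bars is the synergy.
#'
#' @param object A `tcr_info_profile` from [feature_info_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.tcr_info_profile <- function(object, ...) {
  dat <- as_tibble(object) |>
    tidyr::pivot_longer(c("mi_alpha", "mi_beta", "mi_sum", "mi_paired"),
                        names_to = "scope", values_to = "bits") |>
    mutate(scope = factor(.data$scope,
                          levels = c("mi_alpha", "mi_beta", "mi_sum", "mi_paired"),
                          labels = c("alpha", "beta", "alpha + beta", "paired")))
  ggplot(dat, aes(x = .data$feature_type, y = .data$bits, fill = .data$scope)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    labs(x = NULL, y = "mutual information with lineage (bits)", fill = NULL) +
    theme_minimal()
}

#' Plot cross-validation results
#'
#' ROC curve of the first repeat with the chance diagonal.
#'
#' @param object A `tcr_cv` from [cross_validate()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.tcr_cv <- function(object, ...) {
  roc <- attr(object, "roc")
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("%s classifier (mean AUC %.3f)",
                         attr(object, "mode"), mean(object$auc))) +
    theme_minimal()
}

#' Compare fold-level AUCs across classifier modes
#'
#' @param results Named list of `tcr_cv` results.
#' @return A ggplot (boxplots of fold AUCs per mode).
#' @export
plot_mode_comparison <- function(results) {
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- map_chr(results, ~ attr(.x, "mode"))
  }
  dat <- bind_rows(map(results, as_tibble), .id = "mode")
  ggplot(dat, aes(x = .data$mode, y = .data$auc)) +
    geom_boxplot() +
    labs(x = NULL, y = "fold AUC") +
    theme_minimal()
}

#' Plot a paired-concordance species matrix
#'
#' Tile plot of alpha-chain species vs beta-chain species for pairs with
#' both chains annotated; on-diagonal mass means concordant specificity.
#'
#' @param object A `tcr_concordance` from [paired_concordance()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.tcr_concordance <- function(object, ...) {
  ggplot(object$species_matrix,
         aes(x = .data$beta_species, y = .data$alpha_species, fill = .data$n)) +
    geom_tile() +
    scale_fill_gradient(low = "grey95", high = "steelblue4") +
    coord_equal() +
    labs(x = "beta-chain species", y = "alpha-chain species", fill = "pairs") +
    theme_minimal()
}
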