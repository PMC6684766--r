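# Shared constants and small internal helpers.

# 20-letter amino-acid alphabet (one-letter codes).
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join anti_join distinct n rename count pull
#'   across all_of row_number if_else semi_join
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap keep
#' @importFrom stringr str_count str_detect str_split str_to_upper str_trim
#'   str_replace str_squish
#' @importFrom stats p.adjust plogis qlogis rbinom rgeom runif setNames
#'   smooth.spline predict quantile median sd t.test wilcox.test qnorm
#'   rnorm complete.cases lm coef aggregate
NULL

abort_tcr <- function(msg, class = "tcrpair_error") {
  rlang::abort(msg, class = class)
}

is_valid_aa <- function(x) {
  !is.na(x) & nzchar(x) & !str_detect(x, paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"))
}

#' Normalize an IMGT-style gene name
#'
#' Strips allele suffixes (`*01`), trims whitespace, and applies an optional
#' alias table so that gene names from different upstream dialects compare
#' equal.
#'
#' @param x Character vector of gene names.
#' @param aliases Optional named character vector mapping raw names to
#'   canonical names (applied after allele stripping).
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_gene(c("TRBV20-1*01", " TRAV1-2 "))
normalize_gene <- function(x, aliases = NULL) {
  out <- str_trim(as.character(x))
  out <- sub("\\*[0-9]+$", "", out)
  if (!is.null(aliases)) {
    hit <- out %in% names(aliases)
    out[hit] <- unname(aliases[out[hit]])
  }
  out
}

# Clonotype keys. The repertoire key is V gene + CDR3 amino acids; J is kept
# as row metadata only (J-level scans re-deduplicate with J in the key).
alpha_key <- function(v_a, cdr3_a) paste(v_a, cdr3_a, sep = "|")
beta_key <- function(v_b, cdr3_b) paste(v_b, cdr3_b, sep = "|")
paired_key <- function(v_a, cdr3_a, v_b, cdr3_b) {
  paste(alpha_key(v_a, cdr3_a), beta_key(v_b, cdr3_b), sep = "||")
}

# Rank-based AUC of scores for a binary 0/1 label (probability a random
# positive outranks a random negative; ties get half credit).
rank_auc <- function(score, label) {
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Derive a per-stage 32-bit seed from a base seed and a stage tag, so adding
# a stage never perturbs another stage's stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
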