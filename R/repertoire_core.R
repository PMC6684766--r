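# Core data model: paired-clonotype table I/O, cell-level exclusion rules,
# deduplication to unique-clonotype repertoires, and CDR3 primitives.
#
# A cell table has one row per T cell with columns
#   cell_id, subject, lineage (CD4/CD8/unknown), v_a, j_a, cdr3_a,
#   v_b, j_b, cdr3_b, n_alpha_chains, n_beta_chains.
# A repertoire is a tibble of unique clonotypes per lineage, carrying a
# `scope` attribute ("alpha", "beta" or "paired").

DEFAULT_DIALECT <- c(
  cell_id = "cell_id", subject = "subject", lineage = "lineage",
  v_a = "v_a", j_a = "j_a", cdr3_a = "cdr3_a",
  v_b = "v_b", j_b = "j_b", cdr3_b = "cdr3_b",
  n_alpha_chains = "n_alpha_chains", n_beta_chains = "n_beta_chains"
)

#' Read a paired clonotype table
#'
#' Reads a TSV with one row per cell and maps its columns onto the canonical
#' cell-table layout via a dialect (named character vector
#' `canonical = file_column`). Gene names are normalized (allele suffixes
#' stripped), CDR3 strings upper-cased, and rows whose CDR3s fall outside the
#' 20-letter amino-acid alphabet are collected into a validation report
#' (attribute `"validation"`). In strict mode invalid rows are dropped.
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping canonical column names to
#'   the file's column names; defaults cover `cell_id, subject, lineage,
#'   v_a, j_a, cdr3_a, v_b, j_b, cdr3_b`.
#' @param strict If `TRUE`, rows failing validation are excluded; otherwise
#'   they are kept and only reported.
#' @param aliases Optional gene alias table passed to [normalize_gene()].
#' @return A tibble of cells with a `"validation"` attribute (tibble of
#'   line numbers and problems; zero rows when clean).
#' @export
read_clonotype_table <- function(path, dialect = NULL, strict = FALSE,
                                 aliases = NULL) {
  if (!file.exists(path)) abort_tcr(paste0("file not found: ", path))
  dia <- DEFAULT_DIALECT
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("lineage", "v_a", "cdr3_a", "v_b", "cdr3_b")
  missing <- dia[required][!dia[required] %in% names(raw)]
  if (length(missing)) {
    abort_tcr(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
              class = "tcrpair_config_error")
  }
  get_col <- function(canon, default = NA_character_) {
    col <- dia[[canon]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  cells <- tibble(
    cell_id = get_col("cell_id"),
    subject = get_col("subject", "S1"),
    lineage = get_col("lineage"),
    v_a = normalize_gene(get_col("v_a"), aliases),
    j_a = normalize_gene(get_col("j_a"), aliases),
    cdr3_a = str_to_upper(str_trim(get_col("cdr3_a"))),
    v_b = normalize_gene(get_col("v_b"), aliases),
    j_b = normalize_gene(get_col("j_b"), aliases),
    cdr3_b = str_to_upper(str_trim(get_col("cdr3_b"))),
    n_alpha_chains = suppressWarnings(as.integer(get_col("n_alpha_chains", "1"))),
    n_beta_chains = suppressWarnings(as.integer(get_col("n_beta_chains", "1")))
  )
  if (nrow(cells) && anyNA(cells$cell_id)) {
    cells$cell_id <- ifelse(is.na(cells$cell_id),
                            sprintf("cell%06d", seq_len(nrow(cells))),
                            cells$cell_id)
  }
  cells$lineage <- ifelse(is.na(cells$lineage) | cells$lineage == "",
                          "unknown", cells$lineage)
  bad_a <- !is_valid_aa(cells$cdr3_a)
  bad_b <- !is_valid_aa(cells$cdr3_b)
  validation <- tibble(
    line = c(which(bad_a), which(bad_b)) + 1L,  # +1 for the header line
    column = c(rep("cdr3_a", sum(bad_a)), rep("cdr3_b", sum(bad_b))),
    value = c(cells$cdr3_a[bad_a], cells$cdr3_b[bad_b]),
    problem = "CDR3 outside the 20-letter amino-acid alphabet"
  ) |> arrange(.data$line)
  if (strict && nrow(validation)) cells <- cells[!(bad_a | bad_b), ]
  attr(cells, "validation") <- validation
  cells
}

#' Apply cell-level exclusion rules
#'
#' Keeps cells with a CD4/CD8 lineage label and exactly one alpha and one
#' beta chain. Cells lacking a lineage designation, dual-receptor cells
#' (two alpha or two beta chains, indistinguishable from droplet doublets),
#' and unpaired cells (a missing chain) are excluded.
#'
#' @param cells Cell tibble (see [read_clonotype_table()]).
#' @return The kept cells, with an `"exclusions"` attribute: a tibble of
#'   reason (`no_lineage`, `dual_receptor`, `unpaired`) and count.
#' @export
filter_cells <- function(cells) {
  n_a <- cells$n_alpha_chains %||% rep(1L, nrow(cells))
  n_b <- cells$n_beta_chains %||% rep(1L, nrow(cells))
  n_a[is.na(n_a)] <- 1L
  n_b[is.na(n_b)] <- 1L
  unpaired <- n_a == 0L | n_b == 0L | is.na(cells$cdr3_a) | is.na(cells$cdr3_b)
  dual <- !unpaired & (n_a > 1L | n_b > 1L)
  no_lineage <- !unpaired & !dual & !(cells$lineage %in% c("CD4", "CD8"))
  keep <- !(unpaired | dual | no_lineage)
  reasons <- c(no_lineage = sum(no_lineage), dual_receptor = sum(dual),
               unpaired = sum(unpaired))
  report <- tibble(reason = names(reasons), n = as.integer(reasons)) |>
    filter(.data$n > 0L)
  out <- cells[keep, , drop = FALSE]
  attr(out, "exclusions") <- report
  attr(out, "filtered") <- TRUE
  out
}

#' Deduplicate cells to unique-clonotype repertoires
#'
#' Collapses cells to the unique set of clonotypes per lineage at the
#' requested scope, so clonal expansion cannot bias downstream comparisons.
#' The clonotype key is V gene + CDR3 amino acids per chain (paired scope
#' concatenates both chains); set `include_j = TRUE` to add the J gene to
#' the key for J-segment analyses.
#'
#' @param cells Filtered cell tibble.
#' @param scope One of `"alpha"`, `"beta"`, `"paired"`.
#' @param include_j Add J genes to the clonotype key (default `FALSE`).
#' @return A `tcr_repertoire` tibble: one row per unique clonotype per
#'   lineage, with `clone_size` (number of cells) and a `subjects` list
#'   column; the scope is stored in the `"scope"` attribute.
#' @export
deduplicate <- function(cells, scope = c("paired", "alpha", "beta"),
                        include_j = FALSE) {
  scope <- match.arg(scope)
  key <- switch(scope,
    alpha = alpha_key(cells$v_a, cells$cdr3_a),
    beta = beta_key(cells$v_b, cells$cdr3_b),
    paired = paired_key(cells$v_a, cells$cdr3_a, cells$v_b, cells$cdr3_b)
  )
  if (include_j) {
    jpart <- switch(scope,
      alpha = cells$j_a, beta = cells$j_b,
      paired = paste(cells$j_a, cells$j_b, sep = "||")
    )
    key <- paste(key, jpart, sep = "#")
  }
  dat <- as_tibble(cells)
  dat$.key <- key
  dat <- dat |>
    group_by(.data$lineage, .data$.key) |>
    summarise(
      v_a = .data$v_a[1], j_a = .data$j_a[1], cdr3_a = .data$cdr3_a[1],
      v_b = .data$v_b[1], j_b = .data$j_b[1], cdr3_b = .data$cdr3_b[1],
      clone_size = dplyr::n(),
      subjects = list(unique(.data$subject)),
      .groups = "drop"
    ) |>
    rename(key = ".key") |>
    arrange(.data$lineage, .data$key)
  structure(dat, scope = scope, include_j = include_j,
            class = c("tcr_repertoire", class(dat)))
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat("<tcr_repertoire> scope:", attr(x, "scope"), "\n")
  NextMethod()
}

rep_scope <- function(rep) attr(rep, "scope") %||% "paired"

#' Project a paired-scope repertoire onto one chain
#'
#' Derives the single-chain repertoire (unique alpha or beta keys per
#' lineage) directly from the paired repertoire, so the single-chain views
#' describe the same cells.
#'
#' @param rep A paired-scope `tcr_repertoire`.
#' @param chain `"alpha"` or `"beta"`.
#' @return A single-chain `tcr_repertoire`.
#' @export
project_repertoire <- function(rep, chain = c("alpha", "beta")) {
  chain <- match.arg(chain)
  if (rep_scope(rep) != "paired") abort_tcr("projection requires a paired-scope repertoire")
  dat <- as_tibble(rep)
  dat$key <- if (chain == "alpha") {
    alpha_key(rep$v_a, rep$cdr3_a)
  } else {
    beta_key(rep$v_b, rep$cdr3_b)
  }
  dat <- dat |>
    group_by(.data$lineage, .data$key) |>
    summarise(v_a = .data$v_a[1], j_a = .data$j_a[1], cdr3_a = .data$cdr3_a[1],
              v_b = .data$v_b[1], j_b = .data$j_b[1], cdr3_b = .data$cdr3_b[1],
              clone_size = sum(.data$clone_size),
              subjects = list(unique(unlist(.data$subjects))),
              .groups = "drop") |>
    arrange(.data$lineage, .data$key)
  structure(dat, scope = chain, class = c("tcr_repertoire", class(dat)))
}

#' CDR3 net charge
#'
#' Net charge of a CDR3 amino-acid sequence: the count of positively charged
#' residues (R, K) minus the count of negatively charged residues (D, E).
#' Histidine is not counted.
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @return Integer vector of net charges.
#' @export
#' @examples
#' cdr3_charge("CASSLGETQYF")  # -1
cdr3_charge <- function(cdr3_aa) {
  if (any(!is_valid_aa(cdr3_aa))) abort_tcr("invalid amino-acid string in cdr3_charge()")
  as.integer(str_count(cdr3_aa, "[RK]") - str_count(cdr3_aa, "[DE]"))
}

#' CDR3 length
#'
#' Length of the stored CDR3 amino-acid string, inclusive of the proximal
#' cysteine and terminal phenylalanine delimiting the CDR3 region.
#'
#' @inheritParams cdr3_charge
#' @return Integer vector of lengths.
#' @export
cdr3_length <- function(cdr3_aa) {
  if (any(is.na(cdr3_aa) | !nzchar(cdr3_aa))) abort_tcr("empty CDR3 string")
  if (any(!is_valid_aa(cdr3_aa))) abort_tcr("invalid amino-acid string in cdr3_length()")
  nchar(cdr3_aa)
}

#' Amino-acid usage frequencies of a repertoire
#'
#' Frequency of each of the 20 amino acids pooled over all CDR3 residues of
#' the requested chain across the repertoire's clonotypes.
#'
#' @param rep A `tcr_repertoire` (any scope containing the chain).
#' @param chain `"alpha"` or `"beta"`.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_frequencies <- function(rep, chain = c("alpha", "beta")) {
  chain <- match.arg(chain)
  seqs <- if (chain == "alpha") rep$cdr3_a else rep$cdr3_b
  seqs <- seqs[!is.na(seqs)]
  if (!length(seqs)) abort_tcr("empty repertoire in aa_frequencies()")
  counts <- table(factor(unlist(strsplit(seqs, "", fixed = TRUE)), levels = AA_ALPHABET))
  as.vector(counts / sum(counts)) |> setNames(AA_ALPHABET)
}

#' Write the canonical clonotype table
#'
#' One row per unique clonotype per lineage, TSV.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  out <- as_tibble(rep) |>
    mutate(subjects = map_chr(.data$subjects, paste, collapse = ",")) |>
    select(-"key")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
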