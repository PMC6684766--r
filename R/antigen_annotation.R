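# Antigen-specificity annotation against a VDJdb-dialect database keyed by
# V gene + CDR3 amino acids, with paired-concordance classification
# (matched epitope / same species, different epitope / different species)
# and chain-promiscuity reporting.

VDJDB_DIALECT <- c(gene = "gene", cdr3 = "cdr3", epitope = "antigen.epitope",
                   species = "antigen.species", mhc_class = "mhc.class")

#' Load an antigen-specificity database
#'
#' Reads a VDJdb-dialect TSV (columns mappable to gene, CDR3, epitope,
#' species, MHC class), normalizes gene names (allele suffixes stripped)
#' and epitope strings (case, whitespace), infers the chain from the gene
#' prefix (TRA/TRB), and collapses duplicate rows. One chain key may map to
#' several specificities. Records with an unrecognized MHC class are kept
#' with class `"unknown"` and a warning.
#'
#' @param path TSV path, or a data frame already in memory.
#' @param dialect Named character vector mapping canonical names
#'   (`gene, cdr3, epitope, species, mhc_class`) to file columns; the
#'   defaults accept both plain names and VDJdb's dotted names.
#' @param aliases Optional gene alias table for [normalize_gene()].
#' @return A `tcr_annotation_db` tibble: `chain, gene, cdr3, epitope,
#'   species, mhc_class`.
#' @export
load_annotation_db <- function(path, dialect = NULL, aliases = NULL) {
  raw <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  dia <- VDJDB_DIALECT
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  pick <- function(canon) {
    cands <- unique(c(dia[[canon]], canon))
    hit <- cands[cands %in% names(raw)]
    if (!length(hit)) {
      abort_tcr(paste0("annotation database lacks a mappable '", canon, "' column"),
                class = "tcrpair_config_error")
    }
    as.character(raw[[hit[1]]])
  }
  db <- tibble(
    gene = normalize_gene(pick("gene"), aliases),
    cdr3 = str_to_upper(str_trim(pick("cdr3"))),
    epitope = str_to_upper(str_squish(pick("epitope"))),
    species = str_squish(pick("species")),
    mhc_class = pick("mhc_class")
  )
  db$chain <- dplyr::case_when(
    str_detect(db$gene, "^TRA") ~ "alpha",
    str_detect(db$gene, "^TRB") ~ "beta",
    TRUE ~ NA_character_
  )
  if (anyNA(db$chain)) {
    warn("dropping annotation rows whose gene prefix is neither TRA nor TRB")
    db <- db[!is.na(db$chain), ]
  }
  bad_mhc <- !db$mhc_class %in% c("I", "II", "MHCI", "MHCII")
  if (any(bad_mhc)) {
    warn(sprintf("%d annotation rows with unrecognized MHC class kept as 'unknown'",
                 sum(bad_mhc)))
    db$mhc_class[bad_mhc] <- "unknown"
  }
  db$mhc_class <- str_replace(db$mhc_class, "^MHC", "")
  db <- distinct(db[c("chain", "gene", "cdr3", "epitope", "species", "mhc_class")])
  structure(db, class = c("tcr_annotation_db", class(db)))
}

annotations_for <- function(db, chain, gene, cdr3) {
  key_db <- paste(db$chain, db$gene, db$cdr3, sep = "|")
  key_q <- paste(chain, gene, cdr3, sep = "|")
  split(seq_len(nrow(db)), key_db)[key_q]
}

#' Annotation coverage of single-chain repertoires
#'
#' Per lineage and chain: the number and fraction of unique clonotypes with
#' at least one database annotation, with a per-species breakdown.
#'
#' @param rep A single-chain `tcr_repertoire` (alpha or beta scope), or a
#'   paired-scope repertoire (both chains are then reported via projection).
#' @param db A `tcr_annotation_db`.
#' @return Tibble: `chain, lineage, n_clonotypes, n_annotated, fraction`,
#'   with attribute `"species"` (tibble of per-species annotated counts).
#' @export
annotate_single_chains <- function(rep, db) {
  reps <- if (rep_scope(rep) == "paired") {
    list(alpha = project_repertoire(rep, "alpha"),
         beta = project_repertoire(rep, "beta"))
  } else {
    setNames(list(rep), rep_scope(rep))
  }
  cover <- list(); species <- list()
  for (chain in names(reps)) {
    r <- reps[[chain]]
    g <- if (chain == "alpha") r$v_a else r$v_b
    s <- if (chain == "alpha") r$cdr3_a else r$cdr3_b
    hits <- annotations_for(db, chain, g, s)
    annotated <- !vapply(hits, is.null, logical(1))
    cover[[chain]] <- tibble(chain = chain, lineage = r$lineage) |>
      mutate(annotated = annotated) |>
      group_by(.data$chain, .data$lineage) |>
      summarise(n_clonotypes = dplyr::n(), n_annotated = sum(.data$annotated),
                fraction = mean(.data$annotated), .groups = "drop")
    sp <- map(which(annotated), function(i) unique(db$species[hits[[i]]]))
    species[[chain]] <- tibble(chain = chain,
                               lineage = base::rep(r$lineage[annotated], lengths(sp)),
                               species = unlist(sp) %||% character(0))
  }
  out <- bind_rows(cover)
  attr(out, "species") <- bind_rows(species) |>
    count(.data$chain, .data$lineage, .data$species, name = "n_clonotypes")
  out
}

# Concordance status of one pair given its alpha / beta annotation rows.
pair_status <- function(alpha_rows, beta_rows, db) {
  if (is.null(alpha_rows) && is.null(beta_rows)) return("both_unannotated")
  if (is.null(alpha_rows) || is.null(beta_rows)) return("one_annotated")
  ea <- unique(db$epitope[alpha_rows]); eb <- unique(db$epitope[beta_rows])
  if (length(intersect(ea, eb))) return("matched_epitope")
  sa <- unique(db$species[alpha_rows]); sb <- unique(db$species[beta_rows])
  if (length(intersect(sa, sb))) return("same_species_diff_epitope")
  "diff_species"
}

#' Paired antigen-specificity concordance
#'
#' For each unique paired clonotype, looks up both chains in the database
#' and classifies the pair: `matched_epitope` if any alpha annotation
#' shares an epitope with any beta annotation, else
#' `same_species_diff_epitope` if any species coincides, else
#' `diff_species` (precedence: match > same species > different species).
#' Pairs with at most one annotated chain are reported but excluded from
#' the concordance tally.
#'
#' @param rep A paired-scope `tcr_repertoire` (or filtered cells, which are
#'   deduplicated first).
#' @param db A `tcr_annotation_db`.
#' @return A `tcr_concordance` list: `pairs` (per-pair status tibble),
#'   `counts` (tally of the three both-annotated statuses), and
#'   `species_matrix` (alpha species x beta species contingency of
#'   both-annotated pairs).
#' @export
paired_concordance <- function(rep, db) {
  if (!inherits(rep, "tcr_repertoire")) rep <- deduplicate(rep, scope = "paired")
  if (rep_scope(rep) != "paired") abort_tcr("paired_concordance() needs paired scope")
  uniq <- as_tibble(rep) |>
    distinct(.data$v_a, .data$cdr3_a, .data$v_b, .data$cdr3_b)
  hits_a <- annotations_for(db, "alpha", uniq$v_a, uniq$cdr3_a)
  hits_b <- annotations_for(db, "beta", uniq$v_b, uniq$cdr3_b)
  status <- map_chr(seq_len(nrow(uniq)), function(i) {
    pair_status(hits_a[[i]], hits_b[[i]], db)
  })
  pairs <- uniq |>
    mutate(key = paired_key(.data$v_a, .data$cdr3_a, .data$v_b, .data$cdr3_b),
           status = status)
  both <- which(status %in% c("matched_epitope", "same_species_diff_epitope",
                              "diff_species"))
  tallies <- c(matched_epitope = sum(status == "matched_epitope"),
               same_species_diff_epitope = sum(status == "same_species_diff_epitope"),
               diff_species = sum(status == "diff_species"))
  counts <- tibble(status = names(tallies), n = as.integer(tallies))
  sp_pairs <- map(both, function(i) {
    expand.grid(alpha_species = unique(db$species[hits_a[[i]]]),
                beta_species = unique(db$species[hits_b[[i]]]),
                stringsAsFactors = FALSE)
  })
  species_matrix <- if (length(sp_pairs)) {
    bind_rows(sp_pairs) |> count(.data$alpha_species, .data$beta_species, name = "n")
  } else {
    tibble(alpha_species = character(0), beta_species = character(0), n = integer(0))
  }
  structure(list(pairs = pairs, counts = counts, species_matrix = species_matrix,
                 n_both_annotated = length(both)),
            class = "tcr_concordance")
}

#' @export
print.tcr_concordance <- function(x, ...) {
  cat(sprintf("<tcr_concordance> %d pairs with both chains annotated\n",
              x$n_both_annotated))
  print(x$counts)
  invisible(x)
}

#' Report promiscuous chain pairings
#'
#' Chains appearing in two or more pairs whose partner chains carry
#' annotations: reports each such chain with the set of partner epitopes
#' and flags it when the partners recognize more than one distinct epitope
#' (non-monogamous pairing).
#'
#' @inheritParams paired_concordance
#' @return Tibble: `chain, gene, cdr3, n_pairs, partner_epitopes, flagged`.
#' @export
promiscuity_report <- function(rep, db) {
  if (!inherits(rep, "tcr_repertoire")) rep <- deduplicate(rep, scope = "paired")
  uniq <- as_tibble(rep) |>
    distinct(.data$v_a, .data$cdr3_a, .data$v_b, .data$cdr3_b)
  hits_a <- annotations_for(db, "alpha", uniq$v_a, uniq$cdr3_a)
  hits_b <- annotations_for(db, "beta", uniq$v_b, uniq$cdr3_b)
  one_side <- function(chain) {
    if (chain == "alpha") {
      key <- alpha_key(uniq$v_a, uniq$cdr3_a)
      gene <- uniq$v_a; cdr3 <- uniq$cdr3_a; partner_hits <- hits_b
    } else {
      key <- beta_key(uniq$v_b, uniq$cdr3_b)
      gene <- uniq$v_b; cdr3 <- uniq$cdr3_b; partner_hits <- hits_a
    }
    tibble(chain = chain, key = key, gene = gene, cdr3 = cdr3,
           partner_epitopes = map(partner_hits, ~ unique(db$epitope[.x]))) |>
      group_by(.data$chain, .data$key, .data$gene, .data$cdr3) |>
      summarise(n_pairs = dplyr::n(),
                partner_epitopes = list(sort(unique(unlist(.data$partner_epitopes)))),
                .groups = "drop") |>
      filter(.data$n_pairs >= 2) |>
      mutate(flagged = lengths(.data$partner_epitopes) > 1)
  }
  bind_rows(one_side("alpha"), one_side("beta")) |> select(-"key")
}
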