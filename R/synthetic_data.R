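# Synthetic paired CD4/CD8 repertoire generator with planted, recoverable
# statistical structure: lineage-conditional V/J usage (configurable
# log-odds effects), a Valpha x Vbeta interaction (planted synergy), a CDR3
# charge effect, clonal expansion, clones shared between lineages with
# shorter CDR3s, dual-receptor cells, and unlabeled cells.
#
# Causal model, per clone:
#   genes ~ categorical;  CDR3 ~ per-chain length + composition model;
#   lineage ~ Bernoulli( plogis(mu + a[Va] + b[Vb] + c[Va:Vb]
#                               + gamma * (charge_a + charge_b)
#                               + delta * centered CDR3 lengths) ).
# Because lineage is the terminal node, every planted effect has an exact
# conditional log-odds interpretation, and with all other effects zero the
# marginal CD4:CD8 odds ratio of a gene equals exp(its planted effect).

# Zipf-like usage weights for a gene universe of size k.
zipf_probs <- function(k, s = 0.7) {
  w <- (seq_len(k))^(-s)
  w / sum(w)
}

# Discretized-normal length distribution on [lo, hi].
dnorm_lengths <- function(mean, sd, lo = 8L, hi = 22L) {
  supp <- lo:hi
  w <- stats::dnorm(supp, mean, sd)
  setNames(w / sum(w), supp)
}

# Loose CDR3 interior composition (common residues up-weighted).
default_aa_weights <- function() {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  w[c("S", "G", "A", "L", "T")] <- c(3.0, 2.6, 1.8, 1.6, 1.5)
  w[c("Q", "N", "Y", "E", "D", "R", "K")] <- c(1.4, 1.3, 1.3, 1.2, 1.1, 1.1, 1.0)
  w[c("C", "W", "M")] <- c(0.3, 0.3, 0.4)
  w / sum(w)
}

#' Configuration for the synthetic paired-repertoire generator
#'
#' Defaults describe a desk-scale but realistically structured experiment:
#' seven subjects, a 60/40 CD4/CD8 split, Zipf-like gene usage over a
#' 30 Valpha x 40 Vbeta (20 Jalpha, 13 Jbeta) universe, CDR3 lengths from
#' discretized normals (alpha mean 13, beta mean 14.5, sd 1.5, flanking C/F
#' included), geometric clonal expansion, and mild planted structure: a few
#' single-chain V effects of magnitude log 2, a few Valpha x Vbeta
#' interactions of magnitude log 3, and a CDR3 charge effect of 0.1 log-odds
#' per unit net charge (CD4 bias toward positive charge).
#'
#' @param n_cells Number of cells before filtering.
#' @param seed Integer seed; mandatory, the run is fully reproducible from it.
#' @param p_cd4 Baseline CD4 probability (sets the logistic intercept).
#' @param n_subjects Number of subjects cells are spread over.
#' @param v_alpha_probs,v_beta_probs,j_alpha_probs,j_beta_probs Named
#'   categorical usage distributions (must sum to 1).
#' @param a,b Named per-gene log-odds effects for Valpha / Vbeta
#'   (unnamed genes have effect 0).
#' @param c_ab Named Valpha x Vbeta interaction effects, names `"TRAVx:TRBVy"`.
#' @param gamma Log-odds effect per unit total CDR3 net charge.
#' @param delta Length effects, `c(alpha=, beta=)`, per residue from the
#'   chain's mean length.
#' @param length_dist_alpha,length_dist_beta Named probability vectors over
#'   integer CDR3 lengths.
#' @param aa_weights Named composition weights over the 20 amino acids for
#'   CDR3 interior positions.
#' @param expansion_prob Geometric clone-size parameter; clone size is
#'   `1 + rgeom(expansion_prob)`.
#' @param alpha_pool_frac,beta_pool_frac Chain-pool sizes as a fraction of
#'   the clone count. Clones sample their alpha (beta) chain from a finite
#'   pool, so distinct clones can converge on the same single chain — the
#'   mechanism behind single-chain repertoire overlap exceeding paired
#'   overlap. `NULL` disables pooling (every clone draws fresh chains).
#' @param f_shared Fraction of clones planted in both lineages.
#' @param shared_length_shift Planted shared clones draw CDR3 lengths this
#'   many residues shorter (both chains).
#' @param f_dual Fraction of cells given a second receptor chain.
#' @param f_unlabeled Fraction of cells with lineage left unknown.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_cells = 10000, seed,
                       p_cd4 = 0.6, n_subjects = 7,
                       v_alpha_probs = setNames(zipf_probs(30), sprintf("TRAV%d", 1:30)),
                       v_beta_probs = setNames(zipf_probs(40), sprintf("TRBV%d", 1:40)),
                       j_alpha_probs = setNames(zipf_probs(20, 0.4), sprintf("TRAJ%d", 1:20)),
                       j_beta_probs = setNames(zipf_probs(13, 0.4), sprintf("TRBJ%d", 1:13)),
                       a = c(TRAV1 = log(2), TRAV2 = -log(2)),
                       b = c(TRBV1 = log(2), TRBV2 = -log(2)),
                       c_ab = c("TRAV3:TRBV3" = log(3), "TRAV3:TRBV4" = -log(3),
                                "TRAV4:TRBV3" = -log(3), "TRAV4:TRBV4" = log(3)),
                       gamma = 0.1,
                       delta = c(alpha = 0, beta = 0),
                       length_dist_alpha = dnorm_lengths(13, 1.5),
                       length_dist_beta = dnorm_lengths(14.5, 1.5),
                       aa_weights = default_aa_weights(),
                       expansion_prob = 0.75,
                       alpha_pool_frac = 0.8, beta_pool_frac = 1.0,
                       f_shared = 0.01, shared_length_shift = 2L,
                       f_dual = 0.02, f_unlabeled = 0.03) {
  if (missing(seed)) abort_tcr("sim_config() requires an explicit seed")
  cfg <- list(
    n_cells = as.integer(n_cells), seed = as.integer(seed), p_cd4 = p_cd4,
    n_subjects = as.integer(n_subjects),
    v_alpha_probs = v_alpha_probs, v_beta_probs = v_beta_probs,
    j_alpha_probs = j_alpha_probs, j_beta_probs = j_beta_probs,
    a = a, b = b, c_ab = c_ab, gamma = gamma, delta = delta,
    length_dist_alpha = length_dist_alpha, length_dist_beta = length_dist_beta,
    aa_weights = aa_weights, expansion_prob = expansion_prob,
    alpha_pool_frac = alpha_pool_frac, beta_pool_frac = beta_pool_frac,
    f_shared = f_shared, shared_length_shift = as.integer(shared_length_shift),
    f_dual = f_dual, f_unlabeled = f_unlabeled
  )
  for (nm in c("alpha_pool_frac", "beta_pool_frac")) {
    if (!is.null(cfg[[nm]]) && (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)) {
      abort_tcr(paste0(nm, " must be a positive fraction or NULL"),
                class = "tcrpair_config_error")
    }
  }
  for (nm in c("v_alpha_probs", "v_beta_probs", "j_alpha_probs", "j_beta_probs")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-9) {
      abort_tcr(paste0(nm, " must sum to 1"), class = "tcrpair_config_error")
    }
  }
  for (nm in c("f_shared", "f_dual", "f_unlabeled", "p_cd4")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort_tcr(paste0(nm, " must lie in [0, 1]"), class = "tcrpair_config_error")
    }
  }
  bad_a <- setdiff(names(cfg$a), names(cfg$v_alpha_probs))
  bad_b <- setdiff(names(cfg$b), names(cfg$v_beta_probs))
  bad_c <- names(cfg$c_ab)[!vapply(str_split(names(cfg$c_ab), ":"), function(p) {
    length(p) == 2 && p[1] %in% names(cfg$v_alpha_probs) && p[2] %in% names(cfg$v_beta_probs)
  }, logical(1))]
  if (length(c(bad_a, bad_b, bad_c))) {
    abort_tcr(paste0("effect names outside the gene universe: ",
                     paste(c(bad_a, bad_b, bad_c), collapse = ", ")),
              class = "tcrpair_config_error")
  }
  structure(cfg, class = "sim_config")
}

# Draw n CDR3s: "C" + (L-2) interior residues + "F".
draw_cdr3 <- function(n, lengths, aa_weights) {
  inner_len <- pmax(lengths - 2L, 1L)
  res <- sample(AA_ALPHABET, sum(inner_len), replace = TRUE, prob = aa_weights)
  grp <- rep.int(seq_len(n), inner_len)
  inner <- vapply(split(res, grp), paste, character(1), collapse = "")
  paste0("C", inner, "F")
}

sample_lengths <- function(n, dist, shift = 0L) {
  supp <- as.integer(names(dist))
  pmax(sample(supp, n, replace = TRUE, prob = dist) - shift, 6L)
}

#' Generate a synthetic paired CD4/CD8 repertoire
#'
#' Draws clones (genes, CDR3s), assigns each clone's lineage from the
#' configured logistic model, expands clones into cells, plants shared
#' clones in both lineages with shorter CDR3s, and flags dual-receptor and
#' unlabeled cells. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `cells` (one row per cell, ready for
#'   [filter_cells()]) and `truth` (planted effects: `log_or_alpha`,
#'   `log_or_beta`, `interaction`, `gamma`, `delta`, `has_synergy`,
#'   `shared_keys`, plus the config).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  target <- config$n_cells

  # clone sizes (geometric expansion), trimmed so cells sum to target
  sizes <- integer(0)
  while (sum(sizes) < target) {
    sizes <- c(sizes, rgeom(max(64L, ceiling(target / 2)), config$expansion_prob) + 1L)
  }
  k <- which(cumsum(sizes) >= target)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (sum(sizes) - target)
  n_clones <- length(sizes)

  # planted shared clones (never the trimmed last clone; need >= 2 cells)
  n_shared <- round(config$f_shared * n_clones)
  shared <- rep(FALSE, n_clones)
  if (n_shared > 0 && n_clones > 1) {
    shared[sample(n_clones - 1L, min(n_shared, n_clones - 1L))] <- TRUE
    bump <- shared & sizes < 2L
    sizes[bump] <- 2L
    excess <- sum(sizes) - target
    if (excess > 0) {
      for (i in rev(which(!shared))) {
        take <- min(excess, sizes[i] - 1L)
        sizes[i] <- sizes[i] - take
        excess <- excess - take
        if (excess == 0L) break
      }
      keep <- sizes > 0L
      sizes <- sizes[keep]; shared <- shared[keep]
      n_clones <- length(sizes)
    }
  }

  pooled <- function(frac) !is.null(frac) && is.finite(frac) && frac > 0
  if (!pooled(config$alpha_pool_frac) && !pooled(config$beta_pool_frac)) {
    # fresh chains per clone: no single-chain convergence between clones
    v_a <- sample(names(config$v_alpha_probs), n_clones, TRUE, config$v_alpha_probs)
    j_a <- sample(names(config$j_alpha_probs), n_clones, TRUE, config$j_alpha_probs)
    v_b <- sample(names(config$v_beta_probs), n_clones, TRUE, config$v_beta_probs)
    j_b <- sample(names(config$j_beta_probs), n_clones, TRUE, config$j_beta_probs)
    shift <- ifelse(shared, config$shared_length_shift, 0L)
    len_a <- pmax(sample_lengths(n_clones, config$length_dist_alpha) - shift, 6L)
    len_b <- pmax(sample_lengths(n_clones, config$length_dist_beta) - shift, 6L)
    cdr3_a <- draw_cdr3(n_clones, len_a, config$aa_weights)
    cdr3_b <- draw_cdr3(n_clones, len_b, config$aa_weights)
  } else {
    # finite chain pools: distinct clones can reuse a chain (convergent
    # recombination), so single chains are shared more readily than pairs
    draw_chain_pool <- function(frac, v_probs, j_probs, len_dist) {
      n_pool <- max(1L, round((frac %||% 1) * n_clones))
      len <- sample_lengths(n_pool, len_dist)
      list(v = sample(names(v_probs), n_pool, TRUE, v_probs),
           j = sample(names(j_probs), n_pool, TRUE, j_probs),
           len = len, cdr3 = draw_cdr3(n_pool, len, config$aa_weights))
    }
    pa <- draw_chain_pool(config$alpha_pool_frac, config$v_alpha_probs,
                          config$j_alpha_probs, config$length_dist_alpha)
    pb <- draw_chain_pool(config$beta_pool_frac, config$v_beta_probs,
                          config$j_beta_probs, config$length_dist_beta)
    ia <- sample.int(length(pa$v), n_clones, replace = TRUE)
    ib <- sample.int(length(pb$v), n_clones, replace = TRUE)
    v_a <- pa$v[ia]; j_a <- pa$j[ia]; len_a <- pa$len[ia]; cdr3_a <- pa$cdr3[ia]
    v_b <- pb$v[ib]; j_b <- pb$j[ib]; len_b <- pb$len[ib]; cdr3_b <- pb$cdr3[ib]
    if (any(shared)) {
      # planted shared clones carry fresh, shorter chains
      ns <- sum(shared)
      len_a[shared] <- pmax(sample_lengths(ns, config$length_dist_alpha) -
                              config$shared_length_shift, 6L)
      len_b[shared] <- pmax(sample_lengths(ns, config$length_dist_beta) -
                              config$shared_length_shift, 6L)
      cdr3_a[shared] <- draw_cdr3(ns, len_a[shared], config$aa_weights)
      cdr3_b[shared] <- draw_cdr3(ns, len_b[shared], config$aa_weights)
    }
  }
  charge <- cdr3_charge(cdr3_a) + cdr3_charge(cdr3_b)

  eff <- function(tbl, keys) {
    out <- unname(tbl[keys])
    out[is.na(out)] <- 0
    out
  }
  mean_la <- sum(as.integer(names(config$length_dist_alpha)) * config$length_dist_alpha)
  mean_lb <- sum(as.integer(names(config$length_dist_beta)) * config$length_dist_beta)
  eta <- qlogis(config$p_cd4) +
    eff(config$a, v_a) + eff(config$b, v_b) +
    eff(config$c_ab, paste(v_a, v_b, sep = ":")) +
    config$gamma * charge +
    config$delta[["alpha"]] * (len_a - mean_la) +
    config$delta[["beta"]] * (len_b - mean_lb)
  is_cd4 <- runif(n_clones) < plogis(eta)
  subject <- sprintf("S%d", sample.int(config$n_subjects, n_clones, replace = TRUE))

  # expand clones to cells; shared clones contribute to both lineages
  n_cd4 <- ifelse(is_cd4, sizes, 0L)
  n_cd4[shared] <- pmin(pmax(rbinom(sum(shared), sizes[shared], plogis(eta[shared])), 1L),
                        sizes[shared] - 1L)
  cell_lineage <- unlist(map2(n_cd4, sizes, function(k4, s) {
    c(rep("CD4", k4), rep("CD8", s - k4))
  }), use.names = FALSE)
  idx <- rep.int(seq_len(n_clones), sizes)
  cells <- tibble(
    cell_id = sprintf("cell%07d", seq_along(idx)),
    subject = subject[idx],
    lineage = cell_lineage,
    v_a = v_a[idx], j_a = j_a[idx], cdr3_a = cdr3_a[idx],
    v_b = v_b[idx], j_b = j_b[idx], cdr3_b = cdr3_b[idx],
    n_alpha_chains = 1L, n_beta_chains = 1L,
    clone_id = idx
  )

  u <- runif(nrow(cells))
  dual <- u < config$f_dual
  unlabeled <- !dual & u < config$f_dual + config$f_unlabeled
  cells$n_alpha_chains[dual] <- 2L
  cells$lineage[unlabeled] <- "unknown"

  full_a <- setNames(rep(0, length(config$v_alpha_probs)), names(config$v_alpha_probs))
  full_a[names(config$a)] <- config$a
  full_b <- setNames(rep(0, length(config$v_beta_probs)), names(config$v_beta_probs))
  full_b[names(config$b)] <- config$b
  truth <- list(
    log_or_alpha = full_a, log_or_beta = full_b,
    interaction = config$c_ab, gamma = config$gamma, delta = config$delta,
    has_synergy = any(config$c_ab != 0),
    shared_keys = paired_key(v_a[shared], cdr3_a[shared], v_b[shared], cdr3_b[shared]),
    config = config
  )
  list(cells = cells, truth = truth)
}

# Epitope pools per species for the fixture annotation database.
ANNOT_SPECIES <- list(
  CMV = c("NLVPMVATV", "TPRVTGGGAM", "IPSINVHHY"),
  EBV = c("GLCTLVAML", "RAKFKQLL", "YVLDHLIVV"),
  InfluenzaA = c("GILGFVFTL", "PKYVKQNTLKLAT"),
  HIV = c("SLYNTVATL", "ILKEPVHGV"),
  HCV = c("KLVALGINAV"),
  YFV = c("LLWNGPMAV")
)

#' Generate a fixture antigen-specificity database
#'
#' Builds a VDJdb-dialect annotation table (gene, CDR3, epitope, species,
#' MHC class) from a generated repertoire, planting a configured number of
#' fully matched pairs, different-species pairs, and same-species
#' different-epitope pairs, plus single-chain background annotations.
#'
#' @param cells Cell tibble from [generate_repertoire()] (filtered or not).
#' @param n_matched,n_diff_species,n_same_species Numbers of planted pair
#'   types (both chains annotated).
#' @param n_background Extra single-chain (one-sided) annotations.
#' @param seed Integer seed.
#' @return Annotation tibble with columns `gene, cdr3, epitope, species,
#'   mhc_class` and a `"planted"` attribute: tibble of paired clonotype key
#'   and planted concordance status.
#' @export
generate_annotation_db <- function(cells, n_matched = 5, n_diff_species = 2,
                                   n_same_species = 2, n_background = 10, seed) {
  if (missing(seed)) abort_tcr("generate_annotation_db() requires a seed")
  set.seed(seed)
  reps <- cells |>
    filter(.data$lineage %in% c("CD4", "CD8")) |>
    distinct(.data$v_a, .data$cdr3_a, .data$v_b, .data$cdr3_b, .data$lineage)
  n_pairs <- n_matched + n_diff_species + n_same_species
  if (nrow(reps) < n_pairs + n_background) {
    abort_tcr("more annotations requested than available clonotypes")
  }
  pick <- reps[sample.int(nrow(reps), n_pairs + n_background), ]
  mhc_of <- function(lin) ifelse(lin == "CD4", "II", "I")
  multi_epitope <- names(ANNOT_SPECIES)[lengths(ANNOT_SPECIES) >= 2]

  rows <- list(); planted <- list(); r <- 1L
  take <- function(n) {
    out <- pick[r:(r + n - 1L), , drop = FALSE]
    r <<- r + n
    out
  }
  if (n_matched > 0) {
    p <- take(n_matched)
    sp <- sample(names(ANNOT_SPECIES), n_matched, replace = TRUE)
    ep <- map_chr(sp, function(s) sample(ANNOT_SPECIES[[s]], 1))
    rows[[length(rows) + 1L]] <- tibble(
      gene = c(p$v_a, p$v_b), cdr3 = c(p$cdr3_a, p$cdr3_b),
      epitope = rep(ep, 2), species = rep(sp, 2),
      mhc_class = rep(mhc_of(p$lineage), 2)
    )
    planted[[1L]] <- tibble(key = paired_key(p$v_a, p$cdr3_a, p$v_b, p$cdr3_b),
                            status = "matched_epitope")
  }
  if (n_diff_species > 0) {
    p <- take(n_diff_species)
    sp2 <- t(replicate(n_diff_species, sample(names(ANNOT_SPECIES), 2)))
    rows[[length(rows) + 1L]] <- tibble(
      gene = c(p$v_a, p$v_b), cdr3 = c(p$cdr3_a, p$cdr3_b),
      epitope = c(map_chr(sp2[, 1], ~ sample(ANNOT_SPECIES[[.x]], 1)),
                  map_chr(sp2[, 2], ~ sample(ANNOT_SPECIES[[.x]], 1))),
      species = c(sp2[, 1], sp2[, 2]),
      mhc_class = rep(mhc_of(p$lineage), 2)
    )
    planted[[length(planted) + 1L]] <- tibble(
      key = paired_key(p$v_a, p$cdr3_a, p$v_b, p$cdr3_b), status = "diff_species")
  }
  if (n_same_species > 0) {
    p <- take(n_same_species)
    sp <- sample(multi_epitope, n_same_species, replace = TRUE)
    eps <- map(sp, ~ sample(ANNOT_SPECIES[[.x]], 2))
    rows[[length(rows) + 1L]] <- tibble(
      gene = c(p$v_a, p$v_b), cdr3 = c(p$cdr3_a, p$cdr3_b),
      epitope = c(map_chr(eps, 1), map_chr(eps, 2)),
      species = rep(sp, 2),
      mhc_class = rep(mhc_of(p$lineage), 2)
    )
    planted[[length(planted) + 1L]] <- tibble(
      key = paired_key(p$v_a, p$cdr3_a, p$v_b, p$cdr3_b),
      status = "same_species_diff_epitope")
  }
  if (n_background > 0) {
    p <- take(n_background)
    use_alpha <- runif(n_background) < 0.5
    sp <- sample(names(ANNOT_SPECIES), n_background, replace = TRUE)
    rows[[length(rows) + 1L]] <- tibble(
      gene = ifelse(use_alpha, p$v_a, p$v_b),
      cdr3 = ifelse(use_alpha, p$cdr3_a, p$cdr3_b),
      epitope = map_chr(sp, ~ sample(ANNOT_SPECIES[[.x]], 1)),
      species = sp, mhc_class = mhc_of(p$lineage)
    )
  }
  db <- bind_rows(rows) |> distinct()
  attr(db, "planted") <- bind_rows(planted)
  db
}
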