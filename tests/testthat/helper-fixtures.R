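# Small fixtures built in code.

# A hand-written six-cell table exercising every exclusion rule.
tiny_cells <- function() {
  tibble::tibble(
    cell_id = sprintf("c%d", 1:6),
    subject = c("S1", "S1", "S1", "S2", "S2", "S2"),
    lineage = c("CD4", "CD4", "CD8", "unknown", "CD4", "CD8"),
    v_a = c("TRAV1", "TRAV1", "TRAV2", "TRAV1", "TRAV3", "TRAV1"),
    j_a = c("TRAJ1", "TRAJ2", "TRAJ1", "TRAJ1", "TRAJ3", "TRAJ1"),
    cdr3_a = c("CAVMDSSYKLIF", "CAVMDSSYKLIF", "CAASFG", "CAVF", "CILRDF", "CAVMDSSYKLIF"),
    v_b = c("TRBV1", "TRBV1", "TRBV2", "TRBV1", "TRBV3", "TRBV1"),
    j_b = c("TRBJ1", "TRBJ1", "TRBJ2", "TRBJ1", "TRBJ1", "TRBJ1"),
    cdr3_b = c("CASSLGETQYF", "CASSLGETQYF", "CASSF", "CASSF", "CAKRDEF", "CASSLGETQYF"),
    n_alpha_chains = c(1L, 1L, 1L, 1L, 2L, 1L),
    n_beta_chains = 1L
  )
}

# Null generator config: no planted effects of any kind.
null_config <- function(n_cells, seed, ...) {
  sim_config(n_cells = n_cells, seed = seed,
             a = c(TRAV1 = 0), b = c(TRBV1 = 0), c_ab = c("TRAV1:TRBV1" = 0),
             gamma = 0, f_shared = 0, f_dual = 0, f_unlabeled = 0,
             alpha_pool_frac = NULL, beta_pool_frac = NULL, ...)
}

# One planted single-chain effect, everything else null; the marginal
# CD4:CD8 odds ratio of `gene` is then exactly exp(effect).
single_effect_config <- function(n_cells, seed, effect, gene = "TRAV1", ...) {
  sim_config(n_cells = n_cells, seed = seed,
             a = setNames(effect, gene), b = c(TRBV1 = 0),
             c_ab = c("TRAV1:TRBV1" = 0), gamma = 0,
             f_shared = 0, f_dual = 0, f_unlabeled = 0,
             alpha_pool_frac = NULL, beta_pool_frac = NULL, ...)
}

# A checkerboard Valpha x Vbeta interaction over the four most-used genes
# of each chain: strong synergy with no planted single-chain main effects.
synergy_config <- function(n_cells, seed, strength = log(9), ...) {
  pairs <- as.vector(outer(sprintf("TRAV%d", 1:4), sprintf("TRBV%d", 1:4),
                           function(a, b) paste(a, b, sep = ":")))
  signs <- as.vector(outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1)))
  sim_config(n_cells = n_cells, seed = seed,
             a = c(TRAV1 = 0), b = c(TRBV1 = 0),
             c_ab = setNames(signs * strength, pairs), gamma = 0,
             f_shared = 0, f_dual = 0, f_unlabeled = 0,
             alpha_pool_frac = NULL, beta_pool_frac = NULL, ...)
}

# Independent brute-force two-sided Fisher p from log-binomial-coefficient
# arithmetic (no dhyper): used as the enumeration oracle.
oracle_fisher_p2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  dens <- exp(logp)
  min(1, sum(dens[dens <= dens[support == a] * (1 + 1e-7)]))
}
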