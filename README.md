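# tcrpair

Paired αβ T cell receptor (TCR) repertoire analysis, split by CD4+/CD8+
lineage, for immunogenomics work with single-cell paired-chain data.

Most TCR repertoire sequencing reads the β chain alone, implicitly assuming
the αβ pairing carries little information. With paired-chain data one can
ask directly how distinct the CD4+ (MHC class II restricted) and CD8+ (MHC
class I restricted) repertoires are, which receptor features carry the
lineage signal, and whether the *pairing* informs beyond the two chains
separately. `tcrpair` implements that analysis end to end:

- **Repertoire core** — clonotype TSV import with configurable column
  dialects, cell-level exclusion rules (no lineage label, dual-receptor,
  unpaired), deduplication to unique V+CDR3 clonotypes per lineage, and
  CDR3 primitives (length inclusive of the flanking C/F; net charge
  `(#R + #K) − (#D + #E)`).
- **Overlap** — Jaccard index `J = |CD4 ∩ CD8| / |CD4 ∪ CD8|` at α, β, and
  paired scope, pooled and per subject; shared-vs-exclusive CDR3 length
  comparison with bootstrap CIs; a pluggable generation-probability hook.
- **Association scans** — CD4:CD8 odds ratios
  `OR = (a·d)/(b·c)` per feature (V/J genes, Vαβ/Jαβ pairs, CDR3 charge and
  length, and their pairs) with exact two-sided hypergeometric p-values,
  Woolf CIs, Bonferroni control for single-chain scans and Storey q-values
  for the larger paired-scan families.
- **Information theory** — plug-in mutual information
  `I(X; L) = Σ p(x,l) log₂ p(x,l)/(p(x)p(l))` in bits, a finite-sampling
  correction by subsampling extrapolation in 1/N, and the synergy
  decomposition `S = I(Xα, Xβ; L) − I(Xα; L) − I(Xβ; L)`.
- **Lineage classification** — gradient-boosted trees (xgboost) on
  fixed-length clonotype encodings under stratified 5-fold × 10-repeat
  cross-validation, comparing α, β, soft-voting additive (α+β), and joint
  αβ models on fold-level AUCs.
- **Antigen annotation** — VDJdb-dialect databases keyed by V gene + CDR3;
  single-chain coverage, paired specificity concordance (matched epitope /
  same species, different epitope / different species), and promiscuous
  chain reporting.
- **Synthetic generator** — paired CD4/CD8 repertoires with planted,
  exactly recoverable structure (gene-usage log-odds effects, Vα×Vβ
  interactions, charge effects, chain pools for convergent recombination,
  clonal expansion, shared clones with shorter CDR3s, dual-receptor and
  unlabeled cells), so the whole pipeline is testable offline.

Functions take tibbles and return tibbles; results have `tidy()` /
`glance()` and `autoplot()` methods, and `run_tcr_pipeline()` orchestrates
seeded end-to-end runs with a checksummed manifest.

## Worked example

```r
library(tcrpair)

gen   <- generate_repertoire(sim_config(n_cells = 5000, seed = 42))
cells <- filter_cells(gen$cells)
attr(cells, "exclusions")
#>   reason            n
#> 1 no_lineage      141
#> 2 dual_receptor   100

paired <- deduplicate(cells, "paired", include_j = TRUE)
overlap_summary(paired)
#> <tcr_overlap> scope=paired  shared=36  CD4-only=2165  CD8-only=1423
#>   Jaccard = 0.009934   overlap = 0.993% of union

scan <- association_scan(project_repertoire(paired, "alpha"), "v_gene")
glance(scan)
#>   feature_type adjust_method n_features n_significant
#> 1 v_gene       bonferroni            30             2
head(tidy(scan)[order(tidy(scan)$p), c("term", "odds_ratio", "ci_low", "ci_high", "p", "adjusted")], 3)
#>   term   odds_ratio ci_low ci_high           p   adjusted
#> 1 TRAV1       1.87   1.47    2.38  0.000000159 0.00000477
#> 2 TRAV2       0.587  0.457   0.754 0.0000364   0.00109
#> 3 TRAV17      0.631  0.391   1.02  0.0643      1
```

The two significant genes are exactly the two the generator planted:
`TRAV1` with a log-odds effect of `log 2` (estimated OR 1.87, CI covering
2) and `TRAV2` with `−log 2` (estimated OR 0.59, CI covering 0.5). The
paired repertoire shares ~1% of clonotypes between lineages — the planted
shared-clone fraction — while the single-chain repertoires overlap far
more, as chain pooling makes distinct clones converge on the same chain.

```r
feature_info_profile(cells, feature_types = c("v_gene", "charge"),
                     estimator = "corrected", n_boot = 20, seed = 1)
#>   feature_type mi_alpha  mi_beta mi_paired synergy
#> 1 v_gene        0.00550 0.00709     0.0173 0.00471
#> 2 charge        0.0105  0.000428    0.0145 0.00362
```

Each row reports bias-corrected mutual information (bits) between a TCR
feature and lineage for the α chain, β chain, and the joint pair; `synergy`
is the paired value minus the single-chain sum, positive here because the
default configuration plants Vα×Vβ interactions.

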