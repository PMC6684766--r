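---
title: "Methods: paired alpha-beta TCR repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired alpha-beta TCR repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpair)
```

## The scientific problem

During thymic selection a T cell commits to the CD4+ (helper, MHC class II
restricted) or CD8+ (cytotoxic, MHC class I restricted) lineage through the
interaction of its alpha-beta T cell receptor (TCR) with peptide-MHC. Most
repertoire sequencing reads only the beta chain, implicitly assuming the
alpha-beta pairing carries little extra information. With single-cell
paired-chain data one can ask directly: how distinct are the CD4 and CD8
repertoires, which receptor features carry the lineage signal, and does the
*pairing* of chains carry information beyond the two chains separately?

`tcrpair` implements this analysis as composable, tibble-first functions:
clonotype import and exclusion rules, deduplication, repertoire overlap,
odds-ratio feature scans, finite-sample-corrected mutual information with a
synergy decomposition, boosted-tree lineage classification, and
antigen-specificity annotation — together with a synthetic paired-repertoire
generator whose planted structure makes every stage testable without any
external download.

## Data model and exclusion rules

A *cell table* has one row per T cell (subject, lineage, Valpha, Jalpha,
CDR3alpha, Vbeta, Jbeta, CDR3beta, chain counts). Cells lacking a CD4/CD8
label, dual-receptor cells (two alpha or two beta chains; indistinguishable
from droplet doublets), and unpaired cells are excluded by `filter_cells()`,
which reports a per-reason tally.

A *repertoire* is the unique set of clonotypes per lineage at a chosen scope
(alpha, beta, or paired). The clonotype key is **V gene + CDR3 amino-acid
sequence** per chain; J genes are deliberately excluded from the key, and
J-level scans re-deduplicate with J included (`include_j = TRUE`). Counting
each clonotype once prevents clonal expansions from dominating every
downstream statistic. CDR3 length is the stored string length, inclusive of
the conserved flanking cysteine and phenylalanine; CDR3 net charge is
`(#R + #K) - (#D + #E)`, histidine uncounted.

Single-chain repertoires are *projections* of the paired repertoire
(`project_repertoire()`), so the alpha, beta, and paired views describe the
same cells and have comparable sample sizes.

## Overlap

Sharing between the CD4 and CD8 repertoires is quantified by the Jaccard
index `J = |CD4 ∩ CD8| / |CD4 ∪ CD8|`, pooled and per subject, with the
overlap percentage defined on the union (a Venn-style denominator).
`shared_vs_exclusive_lengths()` contrasts mean CDR3 lengths of shared vs
lineage-exclusive clonotypes with a percentile bootstrap (default 10,000
resamples, 99% level — the bootstrap method is a package choice, the level a
convention of this analysis) and a two-sided rank-sum test (normal
approximation with tie correction). `product_rule_gap()` reports
`paired - alpha x beta` overlap as a diagnostic of independent chain
sharing. Generation probabilities are out of scope; `pgen_hook()` only
delegates to a caller-supplied engine, multiplying chain probabilities for
pairs under the independence assumption.

## Odds-ratio feature scans

For a feature `C` (a V or J gene, a Valpha-Vbeta pair, an integer CDR3
charge or length, or a charge/length pair), counts `a, b, c, d` are the CD4
clonotypes with/without `C` and the CD8 clonotypes with/without it, and

    OR = (a * d) / (b * c),

so OR > 1 marks a CD4 bias. The p-value is the exact two-sided
hypergeometric tail (all tables with the observed margins whose probability
does not exceed the observed table's); the 95% CI is the Woolf normal
approximation on log OR with a Haldane–Anscombe 0.5 correction when any
cell is zero. The sample OR (not the conditional MLE) is reported so the
estimate satisfies the definition above exactly; features seen in only one
lineage get `OR = Inf` and are excluded from strength comparisons, where
`|log OR|` is undefined.

Multiple testing follows the family size: single-chain scans (at most a few
dozen tests) use Bonferroni; paired scans (hundreds to thousands of feature
pairs) use q-values — Storey's estimator with a lambda grid of 0 to 0.95 in
steps of 0.05 and cubic-spline pi0 smoothing, falling back to
Benjamini–Hochberg below 100 tests or when pi0 estimation is unstable.
Charge values with a pooled count below 10 are merged into `<=k` / `>=k`
tail bins (per chain for charge pairs) so that exact tests are not run on
near-empty cells. Per-amino-acid usage is compared across subjects with a
one-sample t-test on the log CD4/CD8 usage ratio, Bonferroni-corrected over
the 20 residues; subjects with zero CD8 usage of a residue are excluded
from that residue's test with a warning, and an all-zero log-ratio vector
is reported as p = 1 with a zero-variance flag.

## Mutual information and synergy

Information about lineage `L` in a feature `X` is the plug-in estimate of

    I(X; L) = sum_{x,l} p(x,l) log2( p(x,l) / (p(x) p(l)) )   [bits],

with `0 log 0 = 0`. Plug-in MI is positively biased at finite `N` (first
order: `(|X|-1)(|L|-1) / (2 N ln 2)`). `mi_corrected()` removes most of
this bias by subsampling without replacement at fractions
`{0.5, 0.625, 0.75, 0.875, 1}` (50 replicates per fraction by default),
fitting a quadratic in `1/N` to the per-fraction means, and reporting the
extrapolated intercept; the standard error is the spread of per-replicate
intercepts, which is conservative because subsamples overlap. The
fraction grid and fit degree are a declared package default in the spirit
of standard series-extrapolation practice, and are fully configurable. With
a single fraction the estimator degenerates to the plug-in value and says
so in its diagnostics. Categories with zero marginal count are dropped
before estimation: they contribute nothing but destabilize the
extrapolation fit.

Synergy is `S = I(Xa, Xb; L) - I(Xa; L) - I(Xb; L)`: positive when the
pairing informs beyond its parts (the XOR construction attains +1 bit),
negative under redundancy (two copies of the label attain -1 bit). All
three corrected terms share identical subsample draws (common random
numbers); otherwise the difference of three noisy extrapolations dominates
`S`. `feature_info_profile()` assembles, per feature type, the alpha, beta,
summed (the conditional-independence expectation), and paired estimates
plus `S`.

## Lineage classification

Clonotypes are encoded as fixed-length vectors per chain: one-hot V and J
genes (one-hot keeps the encoding model-agnostic), CDR3 length, CDR3
charge, and the 20 amino-acid usage frequencies. The dataset is the unique
paired clonotype set with cross-lineage clonotypes removed (their label is
ambiguous); every mode — alpha, beta, paired, and the additive ensemble —
uses the same rows and the same stratified 5-fold splits repeated 10 times,
so fold-level AUCs are directly comparable. The additive ensemble trains
separate alpha and beta boosted-tree models and soft-votes (averages) their
predicted CD4 probabilities; if chains contributed independently, it should
match the paired model, so a paired advantage is the classifier-side
signature of synergy. Gradient-boosted trees (xgboost; depth 6, 200 rounds,
eta 0.3, fixed for reproducibility — the defaults favour accuracy over
speed and are reduced in examples) predict the CD4 probability, from which
ROC/AUC and 50%-threshold accuracy are computed. Mode comparisons are
two-sided rank-sum tests on fold-level AUCs (exact at small fold counts
without ties).

## Antigen annotation

A VDJdb-dialect table (gene, CDR3, epitope, species, MHC class) is indexed
by chain + normalized V gene + CDR3; one chain may carry several
specificities. A pair with both chains annotated is classified with the
precedence *matched epitope > same species, different epitope > different
species*: the most charitable reading when chains carry multiple
annotations, and configurable in principle (the underlying per-chain
annotation sets are returned). Epitope equality is exact string match after
case/whitespace normalization; fuzzy CDR3 matching is out of scope. Pairs
with at most one annotated chain never enter the concordance tally.
`promiscuity_report()` flags chains recurring across pairs whose partners
recognize more than one epitope.

## The synthetic generator

`generate_repertoire()` draws clones causally:

1. germline genes from Zipf-like categorical distributions over a synthetic
   universe of 30 Valpha, 40 Vbeta, 20 Jalpha, 13 Jbeta genes (realistic
   cardinalities at desk scale);
2. chains from finite alpha and beta pools (pool sizes default to 0.8 and
   1.0 of the clone count), so distinct clones can converge on the same
   single chain — the analogue of convergent recombination, and the reason
   single-chain overlap between lineages exceeds paired overlap, as in real
   repertoires; pool entries carry a CDR3 whose length comes from a
   discretized normal (alpha mean 13, beta mean 14.5, sd 1.5, support 8–22,
   flanked by C…F) with interior residues from a fixed composition that
   up-weights the residues common in CDR3 loops (setting the pool fractions
   to `NULL` draws fresh chains per clone, the clean iid setting used for
   parameter-recovery checks);
3. lineage from a single logistic model,
   `P(CD4) = logistic(mu + a[Va] + b[Vb] + c[Va,Vb] + gamma * charge
   + delta * centered lengths)`.

Because lineage is the terminal node, every planted coefficient is an exact
conditional log-odds ratio, and with all other effects zero the marginal
CD4:CD8 odds ratio of a gene equals `exp(a)` exactly — the property the
parameter-recovery tests rely on. Lineage-conditional charge and length
differences arise through `gamma` and `delta` rather than through separate
per-lineage CDR3 distributions, which would be circular with a lineage
assigned after the CDR3 is drawn. Clonal expansion is geometric (mean clone
size about 1.3; heavy-tailed expansions are deliberately avoided so
deduplication, not runtime, is what gets exercised). A configured fraction
of clones is planted in both lineages with CDR3 lengths shifted two
residues shorter (shared clones in real repertoires are closer to germline
and shorter); configured fractions of cells are made dual-receptor or left
unlabeled to exercise the exclusion rules. The defaults plant a 60/40
CD4/CD8 split across seven subjects, a few single-chain V effects of
magnitude log 2, a checkerboard of Valpha-Vbeta interactions of magnitude
log 3, and a charge effect of 0.1 — roughly the effect-size regime reported
for real CD4/CD8 repertoires, where single-feature odds ratios rarely
exceed a few fold.

What the generator does *not* emulate: V(D)J recombination biology
(insertion/deletion profiles, generation probabilities), HLA structure
across subjects, sequence similarity clusters of antigen-responding clones,
and heavy-tailed clone sizes. Passing tests therefore demonstrate that the
estimators recover planted statistical structure of the kinds listed above,
not that real repertoires contain such structure.

`generate_annotation_db()` builds a fixture specificity database from a
generated repertoire, planting exact numbers of matched, different-species,
and same-species/different-epitope pairs plus one-sided background
annotations, and records the plant list so annotation results can be
checked for exact recovery.

## Numerical choices and degenerate inputs

- Exact 2x2 p-values enumerate the hypergeometric support and sum
  probabilities at most `(1 + 1e-7)` times the observed table's — the
  customary tie tolerance.
- Jaccard of two empty sets, empty lineage margins, empty repertoires, and
  fewer than two subjects are errors; an empty shared-clone set makes the
  length comparison "not applicable" rather than an error; single-member
  sets flag a degenerate CI.
- Seeds: every stochastic routine takes an explicit seed; the pipeline
  derives per-stage seeds from the global seed and the stage *name*, so
  enabling or disabling one stage cannot perturb another stage's stream.
- Problem sizes in the test-suite simulations (thousands of cells per
  replicate, tens of replicates, reduced boosting rounds) are chosen as
  desk-scale defaults that keep the full parameter-recovery and calibration
  studies comfortably reproducible on a laptop; all are arguments, not
  constants.

## Known limitations

- The bias-corrected MI standard error overstates uncertainty slightly
  (overlapping subsamples), making the null-synergy checks conservative.
- Storey's pi0 spline needs a few hundred tests to be stable; below 100
  tests the scan silently uses Benjamini–Hochberg.
- Infinite odds ratios are reported but cannot enter strength comparisons;
  with very sparse paired features this can drop many significant features.
- The classifier modes share folds by design; this makes mode comparisons
  paired and powerful, but the fold-level AUCs are not independent across
  modes, so the rank-sum test is conservative in one direction and
  anti-conservative in the other at extreme class imbalance.
- Annotation matching is exact on V + CDR3; near-matches (one-residue CDR3
  differences) are counted as unannotated.
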