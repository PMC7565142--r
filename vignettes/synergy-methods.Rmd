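---
title: "Methods: scoring, features and association models in synergyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, features and association models in synergyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscan)
```

# The model

`synergyscan` asks which molecular features of a cancer cell line —
gene expression activity, gene essentiality, and their pathway-level
summaries — are statistically associated with whether a drug pair acts
synergistically in that cell line.

## Synergy scoring

Growth fractions are percent growth relative to an untreated control,
anchored at a time-zero measurement:
$Y = 100\,(T_1 - T_0)/(T_{10} - T_0)$. Negative values mean net cell
kill; values above 100 mean growth beyond control. The Bliss
independence null says two non-interacting drugs combine
multiplicatively on surviving fraction, so the expected combination
growth is $Z = \tilde Y_{A}\tilde Y_{B}/100$ with each monotherapy
fraction truncated at 100 ($\tilde Y = \min(Y, 100)$); when either
monotherapy fraction is non-positive the more lethal drug dominates and
$Z = \min(Y_A, Y_B)$. The ComboScore for one (pair, cell line) is the
mean deviation of observed from expected growth over the dose grid,
$Y_{AB} = \frac1n\sum_{p,q}(Y_{A_pB_q} - Z_{A_pB_q})$, and the binary
synergy status is $S_{AB} = \mathbf 1\{Y_{AB} > 10\}$ — strictly
greater, so a score of exactly 10 is non-synergistic. Missing wells are
dropped from the mean with $n$ reduced accordingly, since the score is
defined as an average over available dose combinations. Replicate
wells, if present, are expected to be averaged upstream by the reader.

When all growth fractions lie in $[0, 100]$ the score is bounded in
$[-100, 100]$ and both extremes are attainable (observed 100 against
expectation 0, and vice versa). The bound is *not* enforced: with
negative observed combination growth (net kill) the mean deviation can
leave the interval, and we deliberately apply no clamping — the
definition above is used verbatim on whatever the assay produced.

A drug pair enters association analysis only when it is synergistic in
at least `min_synergistic = 5` cell lines; recurrence across lines is
required before fitting per-pair models.

## Activity, essentiality and gene filters

A gene is *active* in a cell line when its detection call is present
(`P`). Marginal (`M`) calls are treated as inactive by default — only
confident detection counts — with `marginal_active = TRUE` available
for the permissive reading. Unknown call codes are an error, not a
silent zero.

A gene is *essential* in a cell line when its D2 dependency score is
strictly below −0.5 (D2 is normalized so reference essential genes
average about −1 and controls about 0); −0.5 exactly is non-essential.

Gene filters, applied on the training cohort of $C$ cell lines
(default 43):

* expression genes are kept iff active in **more than** $0.2\,C$ cell
  lines (at 43 lines the cutoff 8.6 means 9 or more) **and** their
  coefficient of variation, $\mathrm{sd}/\mathrm{mean}$ of the
  normalized expression across the training cells, is at least 0.1.
  A non-positive mean leaves the CV undefined and the gene is excluded
  under the CV rule;
* essentiality genes are kept iff essential in at least one training
  cell line. The alternative, keeping only pan-essential genes, is
  available as `essential_rule = "all"`; we default to the
  at-least-one reading because the pan-essential reading leaves almost
  no genes and contradicts the scale of retained gene sets such
  analyses report.

## Features and per-pair designs

Two feature families are computed per cell line (over the post-filter
gene universes by default — the matrices passed in decide, so the
all-gene variant is available by passing unfiltered calls):

* **type 1** (drug-target × cell line): sizes of the union and
  intersection of the pair's two target sets; totals of active and
  essential genes in the cell line; overlap counts of targets with the
  active/essential sets; and the four overlap/total ratios;
* **type 2** (pathway × cell line): counts of the pathway's genes that
  are active/essential in the cell line, their ratios to the cell
  totals, and the pathway size.

Only pathways containing at least one drug-target gene enter the
analysis. Pathway Analysis 1 (PA1) fits one model per pair on type-1
features; PA2 one model per (pair, pathway) on type-2 features; PA3
uses both families. Modes restrict to expression-based,
essentiality-based, or all columns.

Within one pair, columns such as the target-set sizes and the pathway
size are constant across cell lines and cannot enter a regression;
design assembly drops all zero-variance columns (recording them) and
standardizes the rest to zero mean, unit variance. Standardization is
purely numerical conditioning — the reported p-values are invariant to
affine rescaling of predictors. The count/ratio collinearity inherited
from the feature definitions is kept as defined; rank deficiency is
resolved at fit time by dropping aliased columns in declared column
order, deterministically.

## Logistic fits and p-value extraction

Each model regresses the pair's synergy status across training cell
lines on the design. One p-value is reported per model: the two-sided
Wald test of the slope for single-predictor designs, and the
likelihood-ratio test of the full model against the intercept-only
model for multi-predictor designs. At ~43 cell lines with few events,
complete or quasi-complete separation is common; when the ML fit
separates or fails to converge (detected via the fitted-probability
warning, non-convergence, or coefficient magnitudes above 15 on the
standardized scale), the model is refit with Firth's Jeffreys-prior
penalization — implemented as penalized-score IRLS with step-halving —
and a penalized likelihood-ratio p is reported with the `firth_lrt`
method flag; the fallback is never silent. Degenerate designs (no
non-constant columns) and one-class responses yield `NA` p-values with
explicit reasons. ML fits use a deviance tolerance of 1e−12; the Firth
iteration stops when the penalized score drops below 1e−8.

## Aggregation, thresholds and FDR

Per gene, the overall p-value is the minimum over drug pairs; per pair
in the pathway analyses, the minimum over pathways (PA1's single p
passes through). `NA` p-values are ignored by the minimum and excluded
from observed significance counts, but the number of tests stays at the
design count. Bonferroni thresholds are computed exactly as
$\alpha/m$; the genome-wide convenience threshold $10^{-5}$ (close to
0.05/3024 and 0.05/4381 for retained expression and essentiality gene
sets of those sizes) can be supplied directly wherever a threshold
argument is taken. For the pathway analyses the exact value at
$\alpha = 0.05$ over $165 \times 114$ models is $2.66\times10^{-6}$.

FDR tables report, per threshold $t$: the observed count of p-values at
or below $t$ ("at or below" — the distinction from strictly below has
measure zero for continuous p-values), the expected count
$t \times n_\text{tests}$ rounded to two decimals (the precision such
tables are reported at; the unrounded ratio is also emitted as
`fdr_raw`), and their ratio, `NA` when nothing is observed. The
expected counts are the naive global-null expectation; no adjustment is
made for the minimum-p selection at the aggregated level, so
aggregated-level FDRs are optimistic — a known caveat of the design,
reproduced deliberately.

The expression/essentiality comparison reports both Pearson and
Spearman correlations of matched p-value vectors (`NA` below three
complete pairs), Venn counts of significant units at a threshold, and a
target/non-target comparison: per pair, units are labeled *target* when
they belong to (genes) or intersect (pathways) the union of the pair's
target sets, and the two $-\log_{10}p$ distributions are summarized by
quartiles and compared with a two-sided rank-sum test. The choice of
rank-sum statistic here is ours; the comparison is descriptive.

## Hold-out validation

The validation cohort has expression data only. For a chosen (pair,
pathway), the single feature tested is the raw active-gene count of the
pathway per cell line (not the ratio), compared between synergistic and
non-synergistic cell lines by a two-sided Wilcoxon rank-sum test. The
exact null distribution is used when the pooled sample is tie-free and
has at most 20 observations; otherwise the normal approximation with
tie and continuity corrections. The method actually used is always
reported. With an empty group the result is `NA` with a warning —
frequent in small validation cohorts where a pair may have no
synergistic line.

# The synthetic-study generator

`simulate_study()` emulates the five input types at the dimensions of
the motivating study design — 43 training + 16 validation cell lines,
3000 genes, 165 pathways (20–200 genes), 69 drugs with 1–6 targets
each, 114 drug pairs on a 3×3 dose grid:

* per-gene presence probability is Beta(2, 2) (wide spread around 0.5,
  so the 20% presence filter bites realistically); calls are `P` with
  that probability, otherwise `A` with a 5% chance of `M`;
* expression intensities are log-normal with per-gene location drawn
  uniformly on log-scale [4, 8] and scale on [0.2, 0.8], giving CVs
  mostly above the 0.1 filter — the filters remove some but not most
  genes, as in real transcriptome panels;
* D2 scores are a per-gene mixture: essential cells (per-gene fraction
  Beta(1, 9), mean 10%) draw from N(−0.8, 0.2), background from
  N(−0.1, 0.25) — matching the normalization anchors of reference
  essential and control genes;
* monotherapy dose-response follows decreasing logistic curves in dose
  with per-(drug, cell) slope and midpoint, keeping growth fractions in
  (0, 100) while exercising both Bliss branches at extreme doses;
* synergy is planted at the (pair, cell) level through a causal
  pathway's active-gene count — a type-2 expression feature, the family
  the pathway analyses target — via
  $\mathrm{logit}\,P(S=1) = \beta_0 + \beta_1 z$ with $z$ the count
  standardized on the training cells; default $\beta_0 = -1.5$
  (baseline prevalence ≈ 0.18, about 8 of 43 lines) and
  $\beta_1 = 1.2$ (odds ratio ≈ 3.3 per SD). Because the effect enters
  through type-2 features, PA2/PA3 carry signal while PA1 mostly does
  not;
* combination wells are the Bliss expectation **plus**
  $\delta\,S$ plus N(0, `well_noise_sd`) noise (defaults 30 and 5
  growth-fraction units). The sign matters: the ComboScore is defined
  as observed minus expected with synergy called above +10, so a
  planted synergistic well must *raise* observed growth relative to
  expectation to score ≈ +δ. We follow the score's own sign convention
  throughout; δ = 30 against the threshold 10 with noise SE
  $5/\sqrt 9$ makes planted labels recoverable essentially without
  error, which is the point of a positive control;
* the validation cohort shares the gene/pathway structure but has no
  D2 matrix, and ground truth (causal pathway per pair, per-(pair,
  cell) labels, per-gene parameters) is emitted as a sidecar the
  pipeline never reads.

Everything is deterministic given the seed. Infeasible configurations
(pathway larger than the gene universe, more pairs than distinct drug
pairs) fail before generation.

What the generator does **not** emulate: tissue-of-origin structure and
expression correlation between genes, probe-level microarray noise,
shRNA off-target structure, dose-grid irregularities, or batch effects.
Passing tests therefore demonstrate correctness of the statistical
machinery and recoverability of planted effects under clean
assumptions, not performance on real screens.

Named fixtures: `tiny` (6 + 4 cells, 30 genes, 4 pathways, 3 pairs —
hand-checkable set arithmetic), `null` (no pathway-driven effect:
β₁ = 0 and no causal pathways, while δ = 30 keeps synergy itself
present and random with respect to every feature, so scoring and pair
selection still work and fitted p-values are honest nulls), and
`strong_signal` (δ = 40, odds ratio 3.5, half the pairs causal).

# Numerical and testing choices

Test problem sizes are chosen so the whole suite runs in minutes on one
core: the null-calibration check fits ~2,250 pair-pathway models at 43
cell lines and verifies the fraction of p ≤ 0.05 inside the 99%
binomial band; planted-signal recovery uses 50 replicate studies of one
causal pair against 8 pathways; oracle-equivalence checks (brute-force
ComboScore, full rank-sum enumeration up to pooled n = 10, hand-written
IRLS, penalized-likelihood grid search) run on small random instances
with fixed seeds. The ComboScore bound is verified by exhaustive step-1
enumeration of the 1×1 grid (101³ configurations) plus extremal
constructions on larger grids.

# Known limitations

* Minimum-p aggregation with naive expected counts overstates
  aggregated-level significance; treat DD-level FDRs as comparative,
  not calibrated.
* The Firth fallback changes the estimand slightly relative to ML
  fits; mixed method columns should be interpreted with the `method`
  flag in hand.
* Feature ratios are kept alongside their counts by design, so
  per-pair fits are often rank-deficient and resolved by deterministic
  column dropping; coefficients are not interpretable individually.
* The validation test conditions on the pathway chosen on training
  data; its p-values are confirmatory only in the replication sense.
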