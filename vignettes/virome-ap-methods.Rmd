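---
title: "Methods: gut virome profiling and cross-kingdom association analysis"
author: "viromeAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut virome profiling and cross-kingdom association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeAP)
```

## Scope and model of the data

viromeAP analyses case/control gut metagenome cohorts at the level of
viral operational taxonomic units (vOTUs): species-level clusters of
viral genomes against which shotgun reads have been aligned. The
motivating application is acute pancreatitis (AP) versus healthy
controls (HC), with AP cases stratified by severity (MAP < MSAP < SAP)
and etiology, but nothing in the code is disease-specific.

The pipeline has six analysis stages — profiling, ecology, differential
selection, severity trajectories, random-forest diagnostics, and
cross-kingdom networks — plus a synthetic-cohort generator that plants
known effects so each stage can be validated against ground truth
without any raw sequencing data.

## Profiling

Reads are reduced to one best alignment each (highest score; ties broken
by lexicographically smallest vOTU id — a deterministic stand-in for an
aligner's opaque internal tie-breaking, and documented as such). A vOTU
is *present* in a sample only when its best-hit reads cover at least
`breadth_threshold` (default 10%) of the genome; breadth is computed by
interval merging, never per-base arrays. Present vOTUs are quantified as
reads per kilobase (RPK), scaled by the sample's total mapped reads, and
the per-sample vector is renormalized to sum to one after absent vOTUs
are zeroed. Renormalization after presence-filtering is a choice — the
alternative (leave the vector unnormalized) is defensible — and is
flagged in the output file header. Coordinates are 0-based half-open
internally; SAM input (1-based) is converted at the reader boundary.

## Ecology

Alpha diversity reports observed richness, Shannon (natural log — the
base is a convention and is stated here because it changes the numbers),
and Simpson (`1 - sum p^2`). Rarefaction is sample-accumulation (expected
cumulative richness as samples are added), with both a hypergeometric
closed form and a Monte-Carlo mode. Bray–Curtis and Jaccard
dissimilarities, principal coordinates analysis (Gower double-centering
of `-d^2/2`, symmetric eigendecomposition), and one-way PERMANOVA are
implemented from first principles; `vegan` is used in the test suite as
an independent oracle only. PCoA reports negative eigenvalues without
Lingoes/Cailliez correction and computes percent-explained over the
positive eigenvalues only. PERMANOVA p-values use the `+1` correction
(`p = (#{F* >= F} + 1)/(B + 1)`), so `p = 0` is impossible. The test is
unadjusted for covariates; groups that differ in age, sex, or BMI should
be interpreted with the differential module's covariate validation in
hand.

## Differential selection

Per feature, a two-sided Wilcoxon rank-sum test (exact by enumeration
when the pooled sample size is ≤ 12 and tie-free; otherwise a normal
approximation with tie and continuity corrections), Benjamini–Hochberg
adjustment across all tested features, and three filters: BH-q < 0.05,
fold change beyond 1.2 (either direction, with a pseudo-count of 1e-8
guarding zero means), and overall mean relative abundance above 0.01%.
The abundance filter uses the overall mean (the group-wise alternative
is ambiguous in common usage; the choice is fixed and documented here).
BH families are never pooled across feature levels: vOTUs, viral
families, and KOs are each adjusted within their own family of tests.

Covariate validation refits each feature as an ordinary least-squares
model of the arcsine-square-root-transformed relative abundance on the
group indicator plus covariates (age, sex, BMI by default). This is a
deliberate simplification of MaAsLin2-style multivariable validation:
OLS on a variance-stabilized proportion rather than MaAsLin2's default
log-transformed linear model. A feature is `validated` when the group
coefficient is BH-significant and agrees in sign with the Wilcoxon
direction.

KO (auxiliary metabolic gene) carriage between enriched vOTU sets is
tested with a two-sided Fisher exact test via hypergeometric
enumeration, BH across all tested KOs, reporting KOs with occurrence
above 5% in at least one set and q < 0.01. Unfiltered per-direction
counts are also attached, because carriage-direction tallies and the
significant set answer different questions and can differ by orders of
magnitude.

## Severity trajectories

A feature has a monotone severity trajectory when (a) its severity-group
means are strictly ordered along MAP → MSAP → SAP and (b) the Spearman
correlation between per-sample abundance and severity rank is
BH-significant across features. Both criteria and the thresholds are
exposed as arguments. This is a concrete operationalization of
"consistent severity-associated trajectories", which is not a uniquely
defined notion; requiring only ordered means (no trend test) selects
many more features and is available by filtering the returned table on
the means alone. Severity classifiers default to one model per severity
stratum against controls; one-vs-rest is available via `contrast`.

## Random-forest diagnostics

The classifier is a compact random forest (CART trees, Gini impurity,
bootstrap resampling, `mtry = floor(sqrt(p))`) implemented in C++
against R's RNG, so every report is bit-reproducible given (data, seed).
Evaluation is stratified 5-fold cross-validation with 5 repeats; AUC is
computed per fold by the rank statistic (ties get half credit) and
averaged, with pooling per repeat available via `pool_repeats`.
Importance is mean decrease in impurity. The feature-count curve ranks
features *inside each training fold only* and retrains on the top-k, so
selection bias cannot inflate the curve; the suite includes a canary
test on pure-noise data for exactly this leak.

## Cross-kingdom networks

All-pairs Spearman correlations (midranks; t-approximation p-values)
across viral, bacterial and clinical blocks; BH over all tested pairs of
a network pooled (the adjustment scope is a choice — per-block families
would be less conservative); edges kept when |rho| > 0.4 and q < 0.05,
with signs stored. Topology reports average degree `2E/N` over
non-isolated nodes and the unweighted mean shortest path over connected
pairs (a fragmented graph has no finite all-pairs mean, so connected
pairs are the only well-defined denominator). Within-block correlations
are computed but excluded from clinical summaries by default.

## The synthetic world

The generator emulates a two-group cohort shaped like the motivating
study: 82 cases / 115 controls by default, severities split 38:25:19,
etiologies 51:12:7:12, ~85% of vOTUs without family assignment, genome
lengths log-uniform on [2, 100] kb, and 11 named clinical analytes
(WBC, %NEUT, ALT, AST, γ-GT, ALP, TB, DB, CHOL, TG, GLU; additional
placeholders are generated when more are requested, since the remaining
analytes of the full panel are not named in the text).

Abundances are log-normal: a per-feature base level (sd 1) plus
per-sample noise with sd `dispersion` (default 0.7), closed to sum one
per sample. The defaults were calibrated once, at design time, so that
the planted 4-fold effects are detectable at the sensitivities the
acceptance properties assert — a world in which the pipeline's reported
operating characteristics are achievable, as they evidently were in the
motivating study — and are not revisited per test.

Three design points deserve emphasis:

* **Zeros are detection-limit dropouts, not independent coin flips.**
  Per feature, the lowest `sparsity` fraction (default 0.2) of latent
  values is zeroed. Absence calls in real profiled data come from the
  coverage-breadth rule and are therefore abundance-driven; independent
  Bernoulli zeros would also dilute severity trends with dropouts placed
  uniformly across strata, which contradicts the planted "consistent"
  trajectories.
* **Differential effects are planted on baseline-matched pairs.**
  Features are sorted by base abundance and adjacent pairs are split one
  case-enriched / one control-enriched (±`planted_log2fc`/2 each side in
  log2). Unmatched planting lets the planted sets' total community load
  differ by chance between groups, and compositional renormalization
  then leaks that difference into *every* null feature — observed FDR
  reached 0.55 from this artifact alone before matching.
* **Severity gradients are one fold change per step, anchored between
  MAP and MSAP.** Monotone features (drawn from the differential set
  first, ~30% of it by default, mirroring the motivating cohort's ratio
  of trajectory to differential features) change by `planted_log2fc`
  log2 units per severity step. Anchoring at the MAP/MSAP midpoint keeps
  every stratum's case/control contrast non-negative — trajectories
  escalate beyond the group difference rather than erasing it at MAP —
  while the balanced increasing/decreasing sets roughly cancel
  compositionally.

Planted correlation edges couple a partner variable (bacterium or
clinical analyte) to the *normal scores* of the realized viral relative
abundances, so the achieved Spearman correlation tracks
`planted_edge_rho` rather than an attenuated value; partner cells are
exempt from dropout for the same reason. Virus–bacterium edges emanate
from a small viral hub pool (≤ 5 nodes), giving denser planted structure
a higher average degree, the hub-dominated shape of real co-occurrence
networks. Features already used in a virus–bacterium edge are excluded
from clinical coupling so no indirect near-threshold correlations leak
across blocks.

Read alignments are multinomial per sample with probabilities
proportional to abundance × genome length, uniform positions, fixed
100 bp reads, and a configurable fraction of tied secondary hits to
exercise best-hit resolution. There is no nucleotide-level error model —
reads are coordinates, not sequences — and no host-read contamination.

### What a green test does and does not establish

The generator produces log-normal, detection-limit-zeroed,
compositionally closed data with planted monotone structure. Real
viromes additionally have phylogenetically correlated features,
batch/extraction effects, uneven sequencing depth, and presence patterns
driven by strain-level variation; none of these are emulated. Green
recovery tests establish that the *estimators and filters are correct
and well-calibrated in a world matching their own assumptions* — they do
not establish robustness to the violations above, and the type-I results
(PERMANOVA rejection rate, null AUC, null discovery count) are exact
only under exchangeability of the synthetic nulls.

## Numerical choices and degenerate inputs

* Permutation p-values and Fisher/Wilcoxon enumerations use small
  relative tolerances (1e-12 scale) when comparing real-valued
  statistics for ties.
* Empty samples yield zero rows (logged), zero diversity (with a
  warning), and distance 0 to other empty samples by convention.
* Constant features: Wilcoxon returns p = 1; Spearman returns NA and the
  pair is skipped; the OLS validation marks them unvalidated.
* Fold changes use a pseudo-count of 1e-8, four orders of magnitude
  below the abundance filter, so it can never promote a feature.
* BH is order-preserving and capped at 1; it is *not* idempotent
  (re-adjusting adjusted values changes them), so adjusted values are
  never re-adjusted anywhere in the pipeline.

## Known limitations

* The Wilcoxon normal approximation is used for pooled n > 12 even when
  an exact tie-free computation would be feasible; at the cohort sizes
  targeted this is standard practice.
* PERMANOVA supports a single grouping factor; no strata or covariate
  adjustment.
* The random forest is binary-classification only; multi-class severity
  questions are handled as one-vs-control contrasts.
* Network precision/recall guarantees apply to cross-block edges;
  within-block edges among coupled partners of a shared hub are real
  correlations in the generated world and are deliberately not counted
  as errors.
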