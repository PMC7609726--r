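---
title: "Methods: weighted miRNA co-expression modules and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted miRNA co-expression modules and survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircomod)
```

`mircomod` implements a weighted co-expression network workflow for
circulating miRNA discovery cohorts, followed by the statistics used to
validate candidate biomarkers in an independent qPCR cohort. This
vignette is the package's account of the methods: the model and its
assumptions, the tunable parameters and why their defaults are what
they are, the numerical and design choices made where conventions
diverge, and what the synthetic-data generator does and does not
emulate.

## The network model and its assumptions

The substrate is a features-by-samples matrix of log-scale expression
values. The workflow assumes that (i) co-regulation manifests as linear
correlation across samples, (ii) the direction of co-regulation is not
informative for grouping — the network is *unsigned*, built from the
absolute Pearson correlation, so a miRNA suppressed whenever another is
induced belongs to the same module — and (iii) modules are adequately
summarised by one dominant axis of variation (the eigengene).

The stages are:

1. **Similarity** `similarity_matrix()`: `s_ij = |cor(x_i, x_j)|` over
   pairwise-complete samples. Input data are assumed to be on a log
   scale already; the package does not transform intensities.
2. **Soft thresholding** `adjacency_matrix()`, `pick_soft_threshold()`:
   `a_ij = s_ij^beta`. Raising to a power suppresses weak, noise-driven
   correlations smoothly instead of hard-thresholding. `beta` is chosen
   as the smallest integer in 1..20 whose *signed scale-free fit index*
   reaches 0.80 — the index is the R² of the regression of log10 binned
   connectivity frequency on log10 mean connectivity, signed so that a
   decreasing (power-law-like) relationship is positive. Ten
   equal-width connectivity bins are used; a fit with fewer than three
   usable bins (e.g. a regular graph) is reported as invalid (NaN)
   rather than an error. If no power reaches the target, the best
   fitting power is returned with a warning rather than failing the
   run.
3. **Topological overlap** `tom_matrix()`: connection strengths are
   augmented by shared-neighbour structure, which stabilises the
   distance in small cohorts where individual correlations are noisy.
   The stored unit diagonal of the adjacency is excluded from the
   connectivity and shared-neighbour sums. `1 - TOM` is the clustering
   dissimilarity.

## Module detection

`average_linkage()` builds a UPGMA dendrogram of `1 - TOM` (via
`stats::hclust`, which is deterministic). Branch extraction
(`dynamic_cut()`) is where design latitude is largest, and the choice
here matters more than any threshold:

* A *static* cut at a fixed height — whether an absolute height, a
  fraction of the tallest merge, or a quantile of the merge heights —
  is unstable for TOM dissimilarities. The reason is structural: at
  the soft powers that the 0.80 scale-free criterion selects, the TOM
  dissimilarity compresses towards 1, and the merges that join distinct
  modules (and the pure-noise features) bunch within a very narrow band
  near the top of the tree. No single height reliably falls in the gap
  between "within module" and "between modules" across data sets, or
  even across soft powers on one data set.
* `dynamic_cut()` therefore qualifies *branches*, not heights. Every
  subtree is a candidate; it becomes a module when it has at least
  `min_size` leaves **and** it detaches from the rest of the tree well
  above its own top internal merge. The detachment gap (parent merge
  height minus the branch's own height) is normalised by the
  dendrogram's height range (maximum merge height minus its 5th
  percentile), which makes the criterion invariant to the overall
  compression of the scale. The maximal qualifying subtrees become
  modules; everything else is "grey" (unassigned).
* **`min_gap` (default 0.02)**: on factor-model data with planted
  modules the normalised gaps are strongly bimodal — cohesive module
  branches sit around 0.03–0.4, while chance aggregates of noise
  features and branches that mix two modules sit at or below ~0.002.
  The default cuts through the middle of that empty zone with an order
  of magnitude of margin on both sides.
* **`min_size` (default 5)**: the miRNA transcriptome is small and a
  single miRNA can regulate many transcripts, so biologically
  meaningful modules can be tiny; five members is the smallest module
  the pipeline will call.
* **PAM rescue stage**: each grey feature is reassigned to the module
  with the smallest average dissimilarity to its members, but only if
  that average is below the grand mean of within-module
  dissimilarities. This recovers peripheral members dropped by the
  branch criterion without absorbing genuine noise. The reassignment
  uses the pre-rescue memberships, so the result does not depend on
  the order in which grey features are visited.

The whole detection path contains no randomness: identical inputs give
identical modules.

**Merging** (`merge_close_modules()`, default similarity 0.75): module
eigengenes are clustered by average linkage on `1 - cor(ME_a, ME_b)`
and every group linked below height 0.25 is fused, iterating until
stable. "Similarity higher than 75%" is thus read as eigengene
correlation above 0.75, the conventional merge-cut-height semantics.
Merging also serves a second purpose: if the branch criterion splits
one underlying module into fragments, their eigengenes correlate far
above 0.75 and the fragments are re-fused here. Grey is never merged.

**Colours**: modules are named from the canonical ordered palette
(turquoise, blue, brown, ...) by decreasing size, ties broken by
first-seen order; "grey" is reserved for unassigned features; overflow
beyond the palette gets indexed labels.

**Eigengenes** (`module_eigengene()`): member profiles are standardized
(zero mean, unit variance across samples) and the eigengene is the
first right-singular vector of the member-by-sample matrix — one value
per sample, unit norm — with variance explained taken from the squared
singular values. The sign of a principal component is arbitrary, so it
is aligned to correlate positively with the mean standardized member
profile; module–trait correlation signs are therefore reproducible.
Zero-variance members are dropped with a warning; isolated missing
values are mean-imputed after standardization.

## Module–trait analysis and hub ranking

`correlation_test()` computes Pearson correlation on complete pairs and
a two-sided p-value from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees
of freedom; a numerically perfect correlation reports `p = 0`, fewer
than three complete pairs or zero variance are errors.
`module_trait_matrix()` applies this to every (module, trait) pair with
missing trait values handled pairwise. Raw p-values drive module
selection at the conventional 0.05 cut-off; with many modules and many
traits this invites false positives, so a Benjamini–Hochberg-adjusted
column is available (`adjust = "BH"`) and clearly labelled.

Survival enters the discovery phase as a plain numeric trait (observed
months), ignoring censoring — a deliberate simplification matching how
discovery-phase module selection is usually done; censoring is handled
properly in the validation stage.

Gene significance (GS) is stored *signed*, with the conventional
absolute-value reading recoverable as `abs(gs_r)`: ranking positively
and negatively trait-correlated candidates separately requires the
sign. `rank_candidates()` orders each sign group by GS p-value
(ties: larger |GS| first, then feature id) and returns the top
`k = 2` per sign by default. The GS–MM correlation across module
members is reported as the intramodular association statistic; it is
flagged as undefined for modules with fewer than three members or
degenerate member statistics.

## Validation statistics

* **Pfaffl quantification** (`pfaffl_ratio()`,
  `relative_expression()`): ratio =
  `E_t^dCq_t / E_r^dCq_r` with `dCq = Cq(calibrator) - Cq(sample)`.
  Efficiencies default to 2.0 fold/cycle (perfect doubling), in which
  case the ratio is exactly the classic `2^-ddCq`. Replicate Cq values
  are averaged arithmetically before quantification. The default
  calibrator is the across-sample mean Cq, which centres the ratios on
  1; any sample can be named instead.
* **Mann–Whitney** (`mann_whitney()`): two-sided; exact by enumeration
  of all `choose(n_a + n_b, n_a)` rank assignments when the pooled size
  is at most 12 (the enumeration handles ties naturally), otherwise the
  normal approximation with tie and continuity corrections. The
  two-sided exact p-value counts assignments whose U deviates from its
  mean at least as much as observed. Completely tied data give p = 1.
* **OS bins** (`split_by_os()`): `<12`, `[12, 24]`, `>24` months — the
  middle bin closed, the outer bins strict. The three-group expression
  comparison reports *all three* pairwise Mann–Whitney tests plus a
  Kruskal–Wallis omnibus, each labelled, rather than a single
  unattributed p-value.
* **Dichotomisation** (`dichotomize()`): "the mean of the low
  expression group" is circular as a definition, so the package makes
  it well-defined: a provisional low half is everything at or below the
  overall median, the cut-off is the mean of that half, and the final
  groups are high (> cut-off) / low (<= cut-off). This is an
  interpretation and is flagged as such.
* **Survival** (`kaplan_meier()`, `log_rank()`): product-limit
  estimation and the two-group log-rank test are delegated to the
  `survival` package (events precede censorings at tied times). The
  hazard ratio is the O/E estimator `(O1/E1)/(O2/E2)` with
  `exp(log HR ± 1.96 sqrt(1/E1 + 1/E2))` as the 95% CI — a risk-set
  summary consistent with the log-rank statistic, not a fitted
  proportional-hazards model. It is attenuated slightly towards 1
  relative to a Cox estimate; the test suite documents the recovery
  band for a true hazard ratio of 2. Swapping group labels inverts the
  HR and leaves the p-value unchanged.
* The dichotomise-then-test chain uses the data twice, which inflates
  the type-I error above the nominal level; the suite measures this
  inflation on null data and bounds it (≤ 0.10 at nominal 0.05) rather
  than hiding it.

## The synthetic-data generator

`synthetic_design()` describes a Gaussian latent-factor model — the
minimal model satisfying the correlational assumptions of the network
analysis. Each module has an independent standard-normal factor across
samples; member *i* has `x_i = w_i f_m + sqrt(1 - w_i^2) eps_i`, so the
expected within-module correlation between members is `w_i w_j`. By
default 20% of members per module carry negative loadings, exercising
the unsigned-network behaviour. Background features are pure noise.
Traits are `rho f_m + sqrt(1 - rho^2) z` (population correlation
exactly `rho`); survival times are exponential with log hazard
`gamma f_m` and fixed-time censoring, so the true hazard ratio for a
one-SD factor contrast is `exp(gamma)`. qPCR read-out follows the
amplification log-law `Cq = cq0 - log(expr)/log(E)` plus optional
Gaussian noise, emitted in duplicate.

`serum_cohort_design()` is the cohort-scale preset used by the
end-to-end checks: 274 features, 20 samples, 16 modules with sizes
spanning 5 to 46 plus 7 background features, member loading 0.8, and a
clinical block on the sixth-largest module (the "red" position under
size-ordered colouring): survival at rho = −0.59, albumin −0.52, CRP
+0.61, AFP +0.51, nodule count +0.43, alongside liver-function links on
two other modules and two noise traits. The survival *trait* is
generated through the Gaussian link (its correlation with the factor is
exact by construction); the (time, event) pairs for validation come
from the exponential survival model with gamma = 0.7, baseline rate
1/24 per month and censoring at 48 months — plausible figures for an
advanced-cancer cohort followed for four years.

What the generator does **not** emulate: heavy-tailed or non-Gaussian
expression, probe-level array noise, batch effects, correlated factor
hierarchies beyond what a test constructs explicitly, informative
censoring, or qPCR non-detects. Passing tests therefore demonstrate
that the pipeline recovers the structure it assumes; they do not
certify behaviour under real-data pathologies outside that model.

## Numerical choices and degenerate inputs

* Correlations use pairwise-complete observations throughout; a feature
  pair with fewer than three complete samples is an error naming the
  pair.
* Zero-variance features are flagged at read time and dropped (with a
  message) before network construction by the pipeline; zero-variance
  traits are errors naming the trait.
* Symmetry is enforced within 1e-8 on input matrices and restored
  within floating-point error (matrices are symmetrised and clamped to
  [0, 1]) after each construction step; the TOM denominator is asserted
  positive.
* All analysis stages are deterministic; randomness is confined to the
  generators, which derive independent streams for expression, traits
  and survival from one design seed.
* Tie-breaks are fixed everywhere (first-seen order for equal module
  sizes; p-value, then |GS|, then feature id for candidate ranking), so
  reruns are reproducible to the byte.

## Problem sizes used by the test suite

The suite runs at sizes chosen to finish in seconds while keeping the
Monte-Carlo error well inside the asserted bands: 20-node graphs for
the TOM oracle (100 draws), 125-feature / 50-sample data for module
recovery (20 simulations), 10,000 simulations for the correlation and
Mann–Whitney null calibrations, 500 patients per arm for hazard-ratio
recovery (20 simulations), and 20 repetitions of the 274-feature
cohort-scale end-to-end run.

## Known limitations

* Dense TOM only: memory is quadratic in features, appropriate for
  miRNA panels (hundreds of features), not for 10^4+-feature
  transcriptomes.
* Unsigned networks only; signed similarity and robust correlation
  variants (Spearman, biweight midcorrelation) are not implemented.
* No Cox regression with covariates, competing risks, or restricted
  mean survival; the validation layer mirrors the two-group log-rank
  design.
* Equivalence with other dynamic tree cut implementations is not
  promised; module detection is validated by planted-structure
  recovery, not by matching another tool's labels.
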