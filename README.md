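# mircomod

Weighted co-expression network analysis for circulating miRNA biomarker
discovery, with survival validation statistics.

Serum miRNA profiling studies are small: a few hundred detectable miRNAs
measured in a few dozen patients. `mircomod` implements the weighted
gene co-expression network analysis (WGCNA) workflow for exactly this
setting — it groups miRNAs into co-expression modules, correlates the
module summaries with clinical traits (survival months, albumin, CRP,
AFP, tumour staging scores, ...), ranks hub miRNAs inside the most
clinically relevant module, and provides the statistics used to
validate candidates in an independent qRT-PCR cohort (efficiency-
corrected relative quantification, Mann–Whitney group comparisons,
dichotomised Kaplan–Meier survival with log-rank tests and hazard
ratios). A latent-factor synthetic-data generator with planted modules,
trait links and survival links makes the full chain testable without
access to patient data.

## The model

For features *i*, *j* with expression profiles *x<sub>i</sub>*,
*x<sub>j</sub>* across samples:

* **Similarity** (unsigned): *s<sub>ij</sub>* = |cor(*x<sub>i</sub>*,
  *x<sub>j</sub>*)|, so anti-correlated miRNAs are treated as connected.
* **Adjacency**: *a<sub>ij</sub>* = *s<sub>ij</sub><sup>β</sup>*, with
  the soft-thresholding power β chosen as the smallest integer whose
  signed scale-free topology fit index R² reaches 0.80.
* **Topological overlap**:
  TOM<sub>ij</sub> = (*l<sub>ij</sub>* + *a<sub>ij</sub>*) /
  (min(*k<sub>i</sub>*, *k<sub>j</sub>*) + 1 − *a<sub>ij</sub>*), where
  *l<sub>ij</sub>* = Σ<sub>u</sub> *a<sub>iu</sub>a<sub>uj</sub>* and
  *k<sub>i</sub>* is the connectivity; 1 − TOM is the clustering
  distance.
* **Modules**: average-linkage clustering of 1 − TOM followed by a
  deterministic dynamic branch cut (minimum module size 5); unassigned
  miRNAs form the grey bucket. Modules whose eigengenes (first
  principal component of the standardized module expression) correlate
  above 0.75 are merged.
* **Module–trait**: Pearson correlation of eigengenes with traits,
  p-values from the Student transform
  *t* = *r*·√((*n* − 2)/(1 − *r*²)).
* **Hubs**: per-miRNA gene significance (GS, correlation with the
  trait) and module membership (MM, correlation with the eigengene);
  the top candidates per GS sign are reported.
* **Validation**: Pfaffl ratio
  *E*<sub>target</sub><sup>ΔCq,target</sup> /
  *E*<sub>ref</sub><sup>ΔCq,ref</sup>, Mann–Whitney U (exact for small
  samples), Kaplan–Meier / log-rank with HR = (O₁/E₁)/(O₂/E₂).

## Worked example

A discovery cohort at the scale of a serum array study — 274 miRNAs, 20
patients, 16 planted modules, one module carrying a survival signal at
correlation −0.59:

```r
library(mircomod)

des      <- serum_cohort_design(seed = 8)
sim_data <- generate_expression(des)
traits   <- generate_traits(sim_data$truth)

cfg <- pipeline_config(sim_data$expression, traits = traits, seed = 8)
sm  <- run_all(cfg)

sm$beta                  # 10      (smallest power reaching fit R2 >= 0.80)
sm$n_modules             # 16      detected modules
sm$n_grey                # 47      unassigned miRNAs
sm$target_module         # "green" (smallest survival p-value)
sm$target_module_trait   # r = -0.584, p = 0.0069, n = 20
sm$candidates$positive   # "miR-sim-0161" "miR-sim-0160"
sm$candidates$negative   # "miR-sim-0152" "miR-sim-0148"
```

The pipeline recovers the planted survival module: its eigengene
correlates with survival at −0.58 (planted: −0.59), the association is
significant at the 0.05 module-selection cut-off, and hub candidates
are reported for both correlation signs (members with negative factor
loadings flip their GS sign — a direct consequence of the unsigned
network). With `out_dir` set, `run_all()` writes the module assignment,
eigengenes, soft-threshold diagnostics, module–trait table, GS/MM table
and a `summary.json` recording every applied setting.

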