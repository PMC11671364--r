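---
title: "Methods: urinary metabolomics multi-cancer screening and tumor-origin modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary metabolomics multi-cancer screening and tumor-origin modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Urine is an attractive medium for multi-cancer early detection (MCED): it is
collected non-invasively and its metabolome reflects systemic metabolic
reprogramming in lung (LC), gastric (GC) and colorectal (CRC) cancer.
`metaboscreen` implements the full analysis chain such a study needs:

1. **Preprocessing** of per-platform metabolite intensity tables (polar,
   lipid and GC-MS platforms acquired separately).
2. **Panel selection** — ensemble-LASSO with recurring random data splits,
   run per platform and merged.
3. **Screening** — a class-balanced SVM scored continuously and calibrated
   to a fixed specificity, with stage-stratified detection rates.
4. **Tumor-origin prediction** — a two-stage classifier (LC vs non-LC, then
   GC vs CRC) on disjoint biomarker panels.
5. **Pathway over-representation** of the selected panels.
6. A **synthetic-cohort generator** that reproduces the statistical
   structure all of the above assumes, so that every stage is testable
   end-to-end without access to any patient-level data.

Because no raw cohort is distributed with the package, every empirical claim
in this vignette is a property that the test suite or the bundled analysis
scripts compute on generated data.

# The synthetic cohort generator

## What it emulates

`cohort_config()` describes a five-group case-control study (LC, GC, CRC,
non-cancerous disease controls NCD, healthy controls HC) profiled on three
platforms with 125, 13 and 222 metabolites. Its defaults follow the enrolment
structure of a large urinary MCED study: 548/177/186 cancers by type, 563 NCD,
229 HC, a 77/23 discovery/validation split stratified by group, and a
cancer-stage mix of 30.0/11.2/17.2/15.0% for stages I-IV plus 26.6%
non-metastatic with unknown stage. Ages and sexes are drawn per group with
cancer patients older on average (median near 62) — so group-age confounding
is present, as in the emulated study design, while age never enters the
intensity model.

The measurement model is, per platform, for subject $s$ and feature $f$:

$$x_{sf} = 2^{\mu_f + b_{sf} + \delta_{sf}} \cdot d_s \cdot
           \beta_{\mathrm{batch}(s),f} \cdot \varepsilon_{sf}$$

* $\mu_f \sim U(10, 20)$: feature mean log2 abundance;
* $b_{sf} \sim N(0, \sigma_{bio}^2)$: between-subject biological variation,
  `bio_log_sd` = 1.0 on the log2 scale;
* $\delta_{sf}$: the planted group effect (below);
* $d_s = \exp N(0, \sigma_{dil}^2)$: the urine dilution factor, **shared by
  all features and platforms of a sample** (`dilution_log_sd` = 0.5);
* $\beta \sim \exp N(0, \sigma_{batch}^2)$: a per-(batch, feature)
  multiplicative shift (`batch_log_sd` = 0.2);
* $\varepsilon \sim \exp N(0, \sigma_{noise}^2)$: measurement noise
  (`noise_log_sd` = 0.1).

QC rows are generated per batch from one fixed reference profile
($2^{\mu_f}$) plus the batch effect and noise — no dilution, no group
effects. That single shared profile is what makes QC-anchored batch
correction identifiable. The batch layout (4 batches, 3 QC injections each)
is a package default: real acquisition schedules vary and nothing downstream
depends on these numbers, which are exposed in the config.

Missingness combines censoring at low intensity — probability ramping
linearly from `mnar_max_prob` (0.4) at the platform's minimum to zero at the
`mnar_intensity_quantile` (0.15) pooled quantile — with a small MCAR
component (0.01). This is the structure that motivates routing low-intensity
features to half-minimum imputation.

## Planted effects

An `effect_spec()` shifts one metabolite in a set of groups by
`direction * base_log2_effect * stage_multipliers[stage]`. Default stage
multipliers are {I: 0.3, II: 1.0, III: 1.0, IV: 0.6, unknown: 0.8}: muted at
stage I, fully developed at II/III, partly reversed at IV — the trajectory
shape reported for progression-linked urinary markers, and the mechanism by
which the pipeline reproduces the characteristic sensitivity dip at stages I
and IV. The value for "unknown" (a non-metastatic mix) is a package choice
intermediate between the early and late stages. `default_effect_specs()`
plants the study-like marker structure: 18 pan-cancer markers (log2 effect
2), 17 LC-vs-non-LC and 21 GC-vs-CRC markers (log2 effect 1.5), with
alternating signs, spread across the platforms.

Two generator design choices deserve emphasis:

* **Planted markers receive baselines in the 30th-50th percentile of the
  baseline range.** In real urine the total MS signal is dominated by bulk
  compounds (urea, creatinine and the like) that sit orders of magnitude
  above any disease marker, which is exactly why total-signal (MSTUS)
  normalization tracks dilution rather than pathology. A simulation with
  only tens of features would otherwise let a randomly high-abundance marker
  dominate the normalization denominator and leak a spurious per-sample
  shift into every null feature. Mid-low baselines restore the real-data
  regime while keeping markers clear of the low-intensity censoring zone.
* **GC-vs-CRC markers in the origin test conditions are planted
  antisymmetrically** (up $\delta/2$ in GC, down $\delta/2$ in CRC). They
  then carry the full between-class separation $\delta$ for stage 2 while
  being *linearly* uninformative for LC vs non-LC — so the two panels are
  disjoint by signal, not merely by the exclusion rule. A one-sided marker
  (up in GC only) legitimately helps the LC-vs-non-LC stage and would be
  absorbed into panel A.

## What it does not emulate

No raw spectra (m/z, retention time, peak shapes), no annotation or adduct
chemistry, no instrument drift within batch, no correlated metabolite
modules beyond what planting induces, and no age- or sex-dependence of
intensities. Passing tests therefore demonstrate that the *pipeline logic*
is sound under the stated statistical structure — not that any particular
panel would validate in patients.

# Preprocessing

The chain is fixed: **filter → impute → MSTUS → batch-correct → log/scale**
(`preprocess()` / `preprocess_cohort()`), each stage recorded in a report.

* **Detection filter.** A feature detected in less than 80% of subject
  (non-QC) samples is discarded; exactly 80% is kept. The boundary follows
  the strictly-less-than convention (79/100 observed is dropped, 80/100
  kept).
* **Batchwise conditional imputation.** Within each batch — subject and QC
  rows separately — a feature with missing rate ≤ 0.3 *and* mean observed
  intensity above the batch's 25th percentile (both exposed in
  `preprocess_config()`; the routing thresholds are package defaults since
  only the qualitative rule "low missing rate and high intensity" is
  standard) is imputed by iterative chained conditional-mean models on the
  log2 scale: each incomplete feature is regressed on its five most
  correlated neighbours for three rounds, initialised at feature means. The
  imputer draws no posterior noise, so it is deterministic; observed cells
  are never altered, bit-exactly. All other incomplete features take half
  the feature's minimum observed value in the batch — the standard reading
  of censoring below a detection limit. A feature entirely missing within a
  batch falls back to half its global minimum, with a warning.
* **MSTUS normalization.** Each sample is divided by its total useful MS
  signal: the sum over features observed (pre-imputation) in every subject
  sample of the platform ("signals shared by all samples"), falling back to
  all retained features when that set is empty. The operation is exactly
  invariant to per-sample rescaling, which is the dilution-removal contract.
  Normalization runs per platform because platforms are acquired separately,
  and *after* imputation (the ordering is not dictated by the emulated
  protocol; imputing first keeps the denominator defined on complete data,
  and the useful set is computed on the pre-imputation mask either way).
* **QC-anchored batch correction.** In log2 space, each feature in each
  batch is shifted so the batch's QC median matches the grand QC median;
  subject and QC rows get the same correction. This is a deliberate,
  testable stand-in estimator for the general contract "QC-anchored removal
  of batch effects": the adversarial-autoencoder approach used in some
  pipelines buys representation capacity that is irrelevant to the contract
  and untestable at this scale. The `batch_correction_mode` flag leaves room
  for alternative estimators.
* **Log transform and scaling.** log2 (conventional for fold-change
  readouts), then per-feature centering/scaling — unit-variance autoscaling
  by default (standard before penalized regression and SVMs), Pareto
  offered, `"none"` giving the bare transform. Scaling parameters are fitted
  on **discovery subject samples only** and reapplied to validation and QC
  rows; whether the emulated protocol scaled per cohort or globally is
  unstated, and fitting on discovery is the no-leakage choice.

# Panel selection

`ensemble_lasso_select()` implements stability-style selection: for each of
`n_rounds` = 100 recurring random splits, a class-stratified 80% subsample is
fitted with an L1-penalized **logistic** model (`glmnet`), the penalty chosen
by internal 5-fold CV. All endpoints here are binary classifications, so the
logistic likelihood is used even though penalized *linear* regression is
often named generically in this context. A feature's selection frequency is
the fraction of rounds with a nonzero coefficient; the panel keeps features
at frequency ≥ 0.8 ("amalgamating multiple selection systems" is read as
frequency voting — the natural ensemble rule, though other readings exist).
The 1-SE penalty rule is the default (`lambda_rule = "cv-1se"`): it is the
sparser, more conservative choice appropriate for marker discovery, and
`"cv-min"` is available. Class imbalance is handled with inverse-frequency
observation weights, matching the "balanced" modeling used downstream. The
lambda path is floored at 1% of its maximum: with strongly separable planted
effects the unregularized end of the path diverges and never wins the CV.

Determinism and order-invariance: rows are subsampled and folded by index
with per-round derived seeds, so results do not depend on feature column
order; ties in frequency break by larger mean |coefficient|, then feature
id. Raising the threshold can only shrink the panel. Panel sizes are
data-dependent; a `target_size` mode keeps the top-k by frequency instead,
for reproducing fixed-size panels.

`select_per_platform_and_merge()` runs the selector independently per
platform and concatenates (platform-tagged) — feature selection is
per-platform because the platforms are separate assays. `make_disjoint()`
is the set-difference guard for the two origin panels; the origin pipeline
achieves disjointness by construction by passing panel A as the exclusion
set of the panel-B selection.

# Screening

`train_screening_model()` fits a class-weight-balanced SVM (`e1071`,
weights inversely proportional to class frequencies) on the panel features.
Hyperparameters are tuned by 5-fold stratified CV repeated 5 times,
maximizing mean out-of-fold AUC, then the model is refitted on the full
discovery set. The kernel defaults to linear — the study-scale problem has
few features after panel restriction and linear decision scores keep
threshold calibration stable — with the RBF kernel available in the grid.
Decision scores are used raw: the operating point is set empirically on
control scores, so probability calibration is unnecessary here.

`calibrate_threshold()` turns discovery-control scores into an operating
point: the smallest threshold such that the fraction of controls scoring at
or above it is ≤ 1 − target (a sample is positive when score ≥ threshold),
stepping past ties to the midpoint of the next distinct score. Achieved
specificity on the calibration controls is ≥ the target by construction.
The ">99% specificity" operating point is implemented as target 0.99 with
strict exceedance counting. One caveat the package states openly: an
empirical quantile from 500 controls carries a sampling SD of roughly one
percentage point, which is of the same order as the binomial noise of a
2000-control evaluation set — fixed-specificity operating points inherit
that calibration noise, and thresholds in the tests are always calibrated
on discovery controls only (whether the emulated study used discovery or
validation controls is unstated; discovery is the no-leakage choice).

`detection_rate_by_stage()` reports the fraction of cancer samples at or
above threshold per stage with exact Clopper-Pearson 95% CIs; empty strata
are `NA`, never zero. `age_confound_check()` is the Pearson correlation of
scores with age. Note that in the generated cohorts cancer patients are
older by design, so on a mixed validation set this correlation re-measures
the (real) disease signal; computed on controls only it isolates
confounding, and that is what the acceptance script reports.

# Tumor origin

`train_origin_model()` composes two binary stages on disjoint panels:
stage 1 (LC vs GC+CRC) on panel A, stage 2 (GC vs CRC) on panel B selected
with panel A excluded. Both stages are balanced SVMs tuned as in screening.
Because the hierarchy multiplies probabilities, each stage outputs
Platt-calibrated probabilities; the sigmoid is fitted in-package on
out-of-fold decision scores (a deterministic construction — the usual
in-library probability machinery reshuffles folds through a process-global
RNG stream, which would break exact run-to-run reproducibility).
Hierarchical probabilities are exact:

$$P(\mathrm{LC}),\quad (1-P(\mathrm{LC}))\,P(\mathrm{GC}\mid \mathrm{non\text{-}LC}),
\quad (1-P(\mathrm{LC}))\,(1-P(\mathrm{GC}\mid \mathrm{non\text{-}LC}))$$

and sum to 1 per sample by construction. Labels are argmax with the
documented tie priority LC > GC > CRC. The hierarchical mode is the default
because it is the explicitly two-stage structure being modeled and gives
exact probability bookkeeping; `"ovr-stacked"` additionally trains bagged
one-vs-rest scorers (25 bootstrap replicates) on the pooled panel and a
ridge-penalized multinomial stacking combiner over the five base scores —
the smallest standard instantiation of "bagging and stacking" — and is
benchmarked against the hierarchical mode in the tests. How per-class AUCs
were combined in the emulated study is unstated; both modes are provided
rather than asserted.

# Evaluation

`roc_auc()` computes AUC as the Mann-Whitney concordance probability with
ties counted 1/2 (mid-ranks); the test suite checks it against brute-force
pairwise concordance on instances up to 200 samples and against an
independent ROC implementation. The curve convention is score ≥ threshold ⇒
positive, thresholds swept over distinct scores plus the endpoints.
`auc_bootstrap_ci()` is a stratified percentile bootstrap (2000 resamples,
deterministic given a seed) — chosen for distribution-freeness since the CI
method in the emulated analysis is unstated. `confusion_matrix()` reports
counts, per-class recall (the per-cancer detection rate) and accuracy.

# Enrichment

`enrich()` is one-sided hypergeometric over-representation:
$p = P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, with
Benjamini-Hochberg q-values across tested pathways. The significance flag
follows the **raw** p-value at 0.05 — matching the convention of flagging at
p < 0.05 — with q-values reported alongside for the multiplicity-aware
reading. The background universe is configurable because the right choice
is genuinely ambiguous: by default it is the map's annotated set; passing
`universe =` the measured metabolites uses the full reference metabolome as
background, the standard convention when assay coverage is known (and the
one the pipeline driver uses). The bundled map
(`inst/extdata/pathway_map_synthetic.tsv`) is synthetic: 15 KEGG-style
pathways over the generator's default feature ids, constructed so the
default planted markers concentrate in carbohydrate/tryptophan-type
pathways. It exists to exercise the statistics, not to encode biology.

# Numerical choices and degenerate inputs

* All stochastic stages derive their seeds from a global seed via a hash of
  (seed, module name) (`derive_seed()`), keeping modules independent of one
  another's random-number consumption; every derived seed stays below
  $2^{31}$.
* Observed intensities must be strictly positive; zero/negative cells are
  parse or argument errors naming the offending cell.
* A feature constant across discovery samples scales by 1 (not 0) in
  autoscaling.
* An all-features-dropped filter result, a single-class label vector, an
  exclusion set covering all features, a batch without QC in qc-median mode,
  and an empty effective enrichment panel are all explicit errors.
* Threshold calibration with an unreachable target (1 − target < 1/n)
  returns a threshold above the maximum control score, with a warning.

# Problem sizes used by the checks

The acceptance checks run at the sizes their properties need and no larger:
dilution removal on 100 subjects x 30 features; specificity calibration on
500 calibration / 2000 fresh controls; null calibration on 200/arm with 20
permutation repetitions at 30 ensemble rounds; marker recovery on 300/arm
with 5 planted markers among 50 nulls at the full 100 rounds; stage
ordering on an 850-subject cohort (stage strata of 15-60 validation
cancers); origin recovery on 100/class; the demo pipeline on a 270-subject,
78-feature cohort. The criterion-5 cohort and its base effect (1.8 log2)
were sized so that stage II/III sensitivities sit high but unsaturated,
making the stage-I dip and stage-IV reversal orderings meaningful rather
than degenerate at 100%.

# Known limitations

* The generator's group effects are additive on log2 scale and independent
  across features; real metabolite co-regulation is richer, so selection
  stability on real data will be lower than on generated cohorts.
* QC-median correction removes location shifts only; scale (variance)
  batch effects pass through.
* The iterative imputer is a conditional-mean method: it understates
  imputation uncertainty relative to a draws-based MICE, a deliberate trade
  for exact determinism.
* Specificity operating points inherit the calibration-sample noise
  discussed above; at 500 controls, a ±1% deviation of fresh-sample
  specificity from target is expected behavior, not a defect.
* Only the three cancer classes are supported in the origin model; the
  architecture generalizes but is not exercised beyond LC/GC/CRC.
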