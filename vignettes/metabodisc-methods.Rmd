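---
title: "Methods: models, parameters and design choices in metabodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in metabodisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `metabodisc`, the
assumptions behind each stage, the tunable parameters with their
defaults, what the synthetic cohort generator does and does not emulate,
and the design decisions taken where the methodology was genuinely open.

# The analysis problem

The package analyses a samples × metabolites intensity table from an
untargeted LC-MS experiment on a nested case-control cohort: incident
cases, matched controls, and repeated injections of a pooled quality
control (QC) sample. The goal is (i) a multivariate model that
discriminates cases from controls with an honestly estimated AUROC, and
(ii) a short list of metabolites driving the discrimination, with
per-metabolite association statistics. All preprocessing decisions are
encoded in `pipeline_config()` and executed in a fixed order by
`run_pipeline()`:

impute → PQN → glog → autoscale → QC-projection → OPLS-DA (+ Q2,
permutations, Monte-Carlo AUROC) → sPLS-DA → association table.

# Preprocessing

## Missing-value imputation

`impute_missing()` performs iterative truncated-SVD completion: missing
cells start at column means and are repeatedly replaced by the rank-k
reconstruction until the RMS relative change of the imputed cells falls
below `tol` (default 1e-3, `max_iter` 200). The rank k is selected in
[1, `max_rank`] (default 5) by masking an extra `cv_fraction` (default
5%) of *observed* cells and minimizing the reconstruction RMSE on them.
Observed cells are never modified. Low-rank reconstructions of strictly
positive intensity data can dip below zero for low-abundance cells;
imputed cells in strictly positive columns are therefore floored at half
the column's smallest observed value. Without this floor a single
negative reconstruction maps, through the glog, to an extreme outlier
(tens of SDs after scaling) that can dominate the QC PCA. Columns
containing non-positive observed values (arbitrary real matrices) are
left unfloored, so the routine remains a general matrix completer. The
"eigenvector method" label in the metabolomics literature covers several
variants (NIPALS-PCA iteration, SVD iteration); the SVD-iteration form
is implemented here and equivalence with other variants is not claimed.

## Probabilistic quotient normalization

For each sample, the dilution estimate is the median over metabolites of
the ratio to a reference spectrum; all intensities of the sample are
divided by it. The reference is the per-metabolite median over QC
samples when at least 5 QC injections exist, else over all study samples
(`reference = "auto"`). PQN assumes that *most* metabolites are not
differentially abundant, so the median ratio reflects dilution rather
than biology; with 10 discriminant metabolites out of 214 this holds
comfortably. The estimated dilution factors are returned so that
synthetic-truth recovery can be tested (default world: Pearson r ≈ 0.99
against planted factors).

## Generalized logarithm and scaling

The glog transform `log2((x + √(x² + λ))/2)` is strictly increasing,
behaves like `log2(x)` for `x ≫ √λ` and is linear near zero, stabilizing
the variance of low-intensity metabolites. λ defaults to `"auto"` =
(smallest positive entry / 10)²; the value used is recorded in the
result bundle. Scaling (`autoscale()`) centers each metabolite and
divides by its SD; centers and scales are retained and re-applied to
held-out data, never refit on it. The published order of operations
lists normalization, centering/scaling and glog together; scaling before
glog would destroy positivity, so the standard reading — glog before
scaling — is used.

The per-metabolite Shapiro-Wilk screen (`normality_screen()`) is
advisory: it is reported in the result bundle but triggers no filtering,
since no action on its outcome is part of the published workflow.

# QC-based correction of experimental variability

Pooled-QC injections re-measure the same material, so their spread is
experimental. `fit_qc_model()` fits a PCA (column means + first
`n_components` right singular vectors, default 2) on the QC rows of the
scaled table; `remove_qc_variation()` projects every sample (study and
QC) onto the orthogonal complement:
`x ↦ x − ((x − qc_mean)·V)·Vᵀ`. The projection is idempotent, removes
exactly the variance of the projected component (Pythagoras), and is
centered on the *QC* mean, since the subspace is estimated from QC data.
The correction is applied after glog + scaling — the space in which QC
clustering is usually assessed; the published ordering is ambiguous on
this point and the choice is recorded here.

This correction is exactly valid when the nuisance subspace is shared by
QC and study samples and is label-free, which is how the synthetic
generator plants it. Its accuracy is limited by the QC PCA: with n_qc QC
injections, m metabolites and technical noise σ relative to total
variation, the residual nuisance correlation after correction scales
like (σ/σ_total)(1 + √(m/n_qc)) — independent of the nuisance strength,
because a stronger nuisance improves the subspace estimate exactly as
fast as it raises the stakes. With 40 QC samples and 8% technical CV
this leaves a residual correlation of ~0.5 along the true nuisance
directions, while cutting the average per-metabolite nuisance
correlation several-fold (≈0.37 → ≈0.05, the latter at the pure
sampling floor of |r| for n = 418). Tests assert the attainable
behavior: subspace angle < 10°, several-fold reduction, and preservation
of case/control mean differences on discriminant metabolites.

# OPLS-DA

`fit_opls_da()` implements the Trygg-Wold construction with y ∈ {0,1}
centered. Per orthogonal component: `w ∝ Xᵀy` (unit norm), `t = Xw`,
`p = Xᵀt/tᵀt`, `w_o ∝ p − (wᵀp)w`, `t_o = Xw_o`, `p_o = Xᵀt_o/t_oᵀt_o`,
then `X ← X − t_o p_oᵀ`. The predictive component `(w, t, p, c)` is fit
on the filtered matrix; `R2Y = 1 − ‖y − tc‖²/‖y‖²`. Orthogonal scores
are by construction uncorrelated with the centered label (the defining
OPLS property, asserted to 1e-8 in tests), and with 0 orthogonal
components the predictive scores coincide with single-component NIPALS
PLS1. Prediction filters new samples through the stored orthogonal
components, scores them, and thresholds `ŷ = tc + ȳ` at 0.5 — the
natural cut for 0/1 coding; ROC-based outputs never threshold.

`q2_cross_validate()` computes `Q2 = 1 − PRESS/SS` by stratified k-fold
CV (default 7 folds), refitting the centers/scales *and* the model per
training fold. Folds are stratified by class and seeded; a draw that
leaves a one-class training set is re-drawn (at most 100 times).
`permutation_check()` recomputes Q2 under label permutations and reports
`perm_p = (1 + #{Q2_perm ≥ Q2_obs})/(1 + n_perm)` (default 100
permutations). `select_n_orthogonal()` scans 0..`max_orth` (default 6)
and accepts an additional orthogonal component only when it improves Q2
by more than 0.01 — the usual chemometric minimum-improvement rule; a
pure argmax would accrete noise components on clean data. The published
model's four orthogonal components were a data-driven property of the
real cohort and are not reproducible without it; the default is
therefore `"auto"`.

# Validation

`stratified_split()` draws `floor(fraction × class size)` per class
(default 0.7), reproducing the published 102/190 discovery and 44/82
validation arithmetic for 146/272. `monte_carlo_validation()` repeats
split → rescale on discovery → fit → predict validation → AUROC, with
every iteration's seed derived from the master seed (stage-keyed
multiplicative hash, `derive_seed()`), so single iterations are
reproducible in isolation. Scaling parameters are refit on the discovery
half within each iteration (`leakage = "refit"`), the conservative
choice; `"global"` mimics a pre-normalized matrix. The published
workflow used 1000 iterations, which remains the config default; tests
and the acceptance script use 100 to stay inside desk-scale budgets, and
say so.

`roc_analysis()` computes the AUC as the Mann-Whitney statistic (ties
½), its 95% CI from the DeLong placement-value variance, the operating
curve over midpoints between adjacent distinct scores, and the Youden
index by exhaustive scan with ties broken toward higher sensitivity. The
trapezoidal area of the curve and the Mann-Whitney statistic are two
independent code paths and agree to 1e-10 in tests.

# sPLS-DA

`fit_spls_da()` runs PLS on a one-column centered dummy of the label
(equivalent to two-column coding for two classes, with simpler
deflation). Each component's X-weight vector is soft-thresholded —
`u_j ← sign(u_j)(|u_j| − λ)⁺` with λ the (keep+1)-th largest |u_j| — so
exactly `keep` variables survive (the "keepX" order-statistic
convention, rather than a continuous penalty path). Defaults are 5
components × 15 variables. Scores deflate both X and Y, so component
scores are mutually orthogonal. `rank_variables()` scores each
metabolite by max over components of |loading| × (score sum-of-squares
share); unselected metabolites rank last with importance 0.
`cv_error_rate()` uses repeated stratified k-fold CV (5 × 10 by default)
with nearest class-centroid classification in score space — one of the
standard prediction rules for this model family; the published choice of
rule is unstated.

# Association statistics

`ttest_bonferroni()` uses the Welch (unequal-variance) t-test — the
safer default where the published tool's setting is ambiguous — with
`p_adj = min(1, m·p)`. `logistic_or()` fits
`logit P(y=1) = β₀ + β₁x` by IRLS (`stats::glm`, the very routine the
published analysis names), reporting `OR = exp(β₁)` with 95% Wald CI.
Because the pipeline feeds unit-variance scaled data, **ORs are per 1 SD
of the transformed metabolite**; the published work does not state its
unit. Complete or quasi-complete separation is detected (non-convergence,
|β₁| > 20, SE > 50, or saturated fitted probabilities) and raised as an
error rather than reported. Models are unadjusted single-predictor fits;
matched-set conditional logistic regression is out of scope. The fully
processed (scaled, QC-corrected) matrix is the input, a recorded choice
since the published level of processing for these models is unstated.

# The synthetic cohort generator

`generate_cohort()` emulates the *processed-table level* of a cohort
study. Study-sample log-intensities are

baseline μ_j + biological (block-correlated, SD `bio_sd`) +
group effect (cases only, discriminant metabolites only) +
nuisance (rank-r scores × loadings, shared with QC) + iid noise,

and raw intensities are `exp(log-intensity) × dilution`, with QC samples
carrying the pooled mean profile, the nuisance, noise and dilution but
no biology and no group effect. Missingness mixes
completely-at-random and low-intensity-preferential positions
(`mnar_weight`). Effects are additive on the log scale, so they survive
the glog approximately and give predictable odds-ratio signs.

Defaults are the stated world of the cohort being emulated: 146 cases,
272 controls, 40 pooled-QC injections, 214 metabolites, 10 discriminant
metabolites at ±1.5 baseline-SD effects. Where the emulated study
reports no value, parameters were fixed once at levels a practitioner
would call realistic for untargeted plasma LC-MS and then left alone:
`bio_sd = 0.30` (~30% biological CV on the natural-log scale),
`nuisance_sd = 0.30` (structured drift of the same order as biology —
drift is routinely the dominant experimental component),
`noise_sd = 0.08` (~8% technical CV, typical for pooled-QC RSDs),
`dilution_sd = 0.30`, `block_correlation = 0.1` in blocks of ~10
metabolites, `missing_rate = 0.05` with `mnar_weight = 0.4`. A shared
`bio_sd` (rather than per-metabolite scales) keeps the expected
single-metabolite AUC in closed form:
`planted_auc() = Φ(|e|/√2 · 1/√(1 + v))` with
`v = (nuisance_sd² + noise_sd²)/bio_sd²` — 0.769 under the defaults.

What the generator does **not** emulate: chromatographic peak shapes,
retention-time or m/z structure, batch boundaries or run-order drift
curves (the nuisance is static low-rank, not smooth-in-time), matching
covariates (strata are empty; the matched design enters only through
the labels), heteroscedastic per-metabolite technical error, and any
numerical resemblance to the real deposited cohort. A green recovery
test therefore establishes that the pipeline recovers the *planted*
structure under these assumptions — not that it would reproduce the
published real-data values.

# Numerical choices and degenerate inputs

* All randomness flows from one master seed through
  `derive_seed(master, stage, index)` (multiplicative hash mod 2³¹−1),
  so every stage and every MCCV iteration is independently reproducible.
* Fold draws that strand a class are re-drawn (seeded, ≤100 attempts);
  MCCV iterations that fail are re-drawn ≤3 times and counted.
* Zero-variance metabolites abort scaling with the metabolite named;
  all-missing or <2-observed columns abort imputation likewise.
* OPLS weight vectors with zero norm (degenerate X) are an error; an
  orthogonal round that finds no y-orthogonal structure left truncates
  `n_orth` honestly rather than fabricating a component.
* Youden ties break toward higher sensitivity; ranking ties break toward
  the earlier component, then lexicographically, so top-k lists are
  stable.
* JSON serialization writes full double precision (`digits = NA`), so
  result bundles round-trip bit-identically.

# Known limitations

* The QC-projection correction cannot push residual nuisance
  correlation along the true directions below ≈(σ_tech/σ_total)
  (1+√(m/n_qc)) (~0.5 in the default world); see the QC section. This
  is a property of estimating a subspace from finitely many QC
  injections, not of the implementation.
* Q2 and the permutation check refit scaling per fold but share the
  glog λ and imputation with the full table; at 5% missingness the
  leakage through these steps is negligible but nonzero.
* `n_orth = "auto"` inside the default pipeline frequently selects 0 on
  strong synthetic signals — orthogonal variation that is worth a
  component in real cohorts (instrument drift correlated with run
  order) is mostly removed here by the QC projection first.
* The sPLS-DA error rate uses nearest-centroid classification; other
  rules (max-distance, Mahalanobis) can differ by a few points.
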