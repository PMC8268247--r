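# metabodisc

Untargeted plasma-metabolomics biomarker discovery for case/control
cohorts, packaged as a tested, reusable R pipeline.

The package targets the common nested case-control design in which an
LC-MS feature table (samples × identified metabolites, with missing
values and pooled-QC injections) is mined for metabolites that
discriminate incident cases from matched controls. It implements the
full analysis chain:

1. **Missing-value imputation** by iterative truncated-SVD ("eigenvector")
   low-rank completion, with the rank chosen by cross-validation on
   held-out observed cells.
2. **Probabilistic quotient normalization (PQN)** — each sample is divided
   by the median ratio of its spectrum to a reference spectrum (pooled-QC
   median by default), correcting sample-to-sample dilution.
3. **Generalized logarithm (glog)** transform
   `x ↦ log2((x + √(x² + λ))/2)` and per-metabolite centering /
   unit-variance scaling.
4. **QC-based correction**: a 2-component PCA model on the pooled-QC
   samples summarizes structured experimental variability, which is
   removed from every sample by orthogonal projection.
5. **OPLS-DA** (orthogonal projections to latent structures, Trygg–Wold
   construction): variation orthogonal to the class label is deflated
   into separate components before a single predictive component is fit;
   reported with R2Y, 7-fold cross-validated Q2, and a label-permutation
   p-value.
6. **Monte-Carlo cross-validation**: repeated stratified 70/30
   discovery/validation splits; the discovery-only model predicts the
   validation samples and the AUROC distribution (median/min/max) is
   reported. ROC analysis uses the Mann-Whitney AUC with a DeLong 95%
   confidence interval and the Youden index J = max(sens + spec − 1).
7. **sPLS-DA**: sparse PLS-DA whose X-loadings are LASSO soft-thresholded
   so each of 5 components selects exactly 15 metabolites; variables are
   ranked by loading × score-variance share, with a repeated-CV
   nearest-centroid error rate.
8. **Association statistics**: per-metabolite Welch t-tests with
   Bonferroni adjustment, and single-predictor binomial logistic
   regression odds ratios (per 1 SD of the transformed intensity) with
   95% Wald intervals.

A synthetic-cohort generator (`cohort_spec()` / `generate_cohort()`)
produces feature tables with planted ground truth — discriminant
metabolites with signed log-scale effects, per-sample dilution factors, a
low-rank experimental nuisance shared by QC and study samples, and mixed
MCAR/MNAR missingness — so every stage has a recovery-testable input.

## Worked example

```r
library(metabodisc)

cohort <- generate_cohort(cohort_spec(seed = 42))   # 146/272/40 x 214
cfg <- pipeline_config(validation = list(n_iterations = 100L),
                       opls = list(n_permutations = 50L),
                       imputation = list(max_rank = 3L))
bundle <- run_pipeline(cohort$table, cohort$meta, cfg, seed = 1)
print(bundle)
```

```
metabodisc result bundle
  OPLS-DA: 0 orthogonal component(s), R2Y 0.806, Q2 0.742, perm p 0.0196
  MCCV AUROC (100 iter): median 0.994 [0.975, 1.000]
  sPLS-DA error rate: 0.021
  top metabolites: met210, met005, met115, met080, met009
```

Reading this output: the OPLS-DA model explains 81% of the label
variance with a cross-validated Q2 of 0.74, and none of the 50
label permutations reached the observed Q2 (p ≈ 0.02, the permutation
floor 1/51). Across 100 random 70/30 resamplings, the validation-cohort
AUROC has median 0.994 — the planted 10-metabolite signal is easily
recovered at this effect size. The sPLS-DA 5 × 15 model misclassifies
2.1% of samples under repeated 5-fold cross-validation, and its
top-ranked metabolites can be checked against
`cohort$truth$discriminant_ids`. `bundle$association` holds the Welch
t / Bonferroni and odds-ratio table for the top-ranked set.

A command-line wrapper is installed as `exec/metabodisc`
(subcommands `simulate`, `preprocess`, `qc-correct`, `fit`, `validate`,
`select`, `associate`, `run-all`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the
default synthetic cohort — generation, preprocessing, QC correction,
OPLS-DA with permutation check, 100-iteration Monte-Carlo validation,
sPLS-DA selection and association statistics — and writes its JSON
output to the requested path:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
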