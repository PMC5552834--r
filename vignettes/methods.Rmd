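---
title: "Methods: regularised least-squares panel selection for prospective risk cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularised least-squares panel selection for prospective risk cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a prospective cohort, serum metabolite profiles measured at baseline are
used to predict which non-diabetic individuals will progress to type 2
diabetes during follow-up. Two complementary questions arise: *which
individual metabolites are associated* with progression (an inference
problem, answered per feature with covariate-adjusted logistic regression and
false-discovery-rate control), and *how well can a multivariate model
predict* progression, ideally with a small, interpretable marker panel (a
prediction problem, answered with regularised classification, feature
selection and honest cross-validated discrimination statistics). `rlspanel`
implements both arms plus the synthetic-cohort machinery needed to test them
end to end without patient data.

## Models and procedures

### Association screening

Each (standardised) metabolite is tested by maximum-likelihood logistic
regression of the binary progression outcome on the feature, optionally with
clinical covariates as additional terms; the reported odds ratio is per one
standard deviation. Fitting is iteratively reweighted least squares with
convergence declared when the maximal score component falls below `1e-8` or
the relative log-likelihood change below `1e-10` (at most 100 iterations).
Quasi-complete separation is detected (coefficient magnitude above 15 on
standardised predictors with non-decreasing steps) and *flagged*, never
silently reported as an estimate. Confidence intervals and p-values are Wald;
multiplicity is controlled with Storey q-values using the fixed-λ plug-in
`pi0 = #{p > 0.5} / (m/2)` (a `bh = TRUE` switch forces `pi0 = 1`, which is
exactly Benjamini–Hochberg). Baseline cohort characteristics are compared
with Fisher's exact test (categorical) and Welch's t-test (continuous),
including a summary-statistics entry point (n, mean, SEM per group) for
published tables.

### The risk classifier

The risk model is regularised least squares (RLS, i.e. ridge regression on
labels coded +1 for progressors and −1 for non-progressors):
`min_w ||y − Xw − b||² + λ||w||²`, with the intercept b unpenalised
(implemented by centring columns and labels — cohorts are imbalanced, so the
bias term matters). The primal `(XᵀX + λI)⁻¹Xᵀy` and dual
`Xᵀ(XXᵀ + λI)⁻¹y` solutions are both implemented and identical; the cheaper
one is chosen by problem shape. Leave-one-out (LOO) predictions come from
the regularised hat matrix `H = J/n + Xc(XcᵀXc + λI)⁻¹Xcᵀ` via
`loo_i = (ŷ_i − H_ii y_i)/(1 − H_ii)`, which equals explicit retraining to
numerical precision and is what makes greedy selection affordable.

### GreedyRLS

Forward selection starts from the empty set and repeatedly adds the feature
minimising the LOO mean squared error of the RLS model on the augmented set
at fixed λ. The implementation updates the hat diagonal, fitted values and
every candidate's Schur complement in O(np) per step, and is algebraically
identical to naively refitting all candidates at every step (the test suite
holds it to that oracle exactly). Ties break to the lowest column index so
results are reproducible. The selection criterion is pluggable in principle;
LOO-MSE is the default because the closed form makes it exact rather than an
estimate.

### Repeated nested stratified cross-validation

Performance is estimated with R repetitions of 10×10 nested stratified
cross-validation (defaults; both fold counts and R are `cv_plan()`
parameters). Within a repetition, the outer split estimates performance; for
each outer fold, an inner stratified cross-validation on the outer-training
samples picks the grid λ maximising pooled inner out-of-fold AUC (ties to
the smallest λ). When panel selection is enabled, GreedyRLS runs on the
outer-training data at that λ before the refit. Each repetition's ROC/AUC is
built from its pooled out-of-fold scores; the summary is the mean AUC with
2.5/97.5 empirical percentiles across repetitions. Repetition r draws all
its randomness from `seed + r`, so any repetition is reproducible alone.

Three points in this design were genuinely open and resolved as follows:

* *Which λ does GreedyRLS use?* The λ chosen by the inner cross-validation
  of the full-feature model for that outer fold (and, for the per-repetition
  reported panel, the mode of the ten per-fold λ values). This mirrors the
  workflow the design emulates; note it means small panels are selected and
  refit at a λ tuned for a much larger model, which is visible in the
  results (heavily shrunk panel refits).
* *Where does the reported per-repetition feature list come from?* Default
  `selection_scope = "full-cohort"`: GreedyRLS on the entire cohort at the
  repetition's modal λ. The alternative (`"fold-union"`, the union of the
  ten per-fold selections) is implemented and tested.
* *How are repetitions combined for paired model comparisons?* Each sample's
  out-of-fold score is averaged over repetitions, giving one paired vector
  per model for DeLong tests and discrimination slopes (labelled as such in
  reports).

### External transfer

For validation in an independent cohort, each repetition chooses λ by inner
cross-validation on the full training cohort and fits one model on all
training samples; the repetition-wise weight vectors and intercepts are
averaged into a single linear model, which scores the validation cohort
once. The validation cohort is imputed on its own and standardised on its
own scale (different platforms), while model columns are aligned by name.

### Discrimination statistics

AUC is the Mann–Whitney probability (ties count one half) and equals the
trapezoidal ROC area. DeLong's structural-component method provides the test
for two correlated AUCs and the single-AUC confidence interval. Risk scores
are converted to probabilities by `p = plogis(score / SD)`, where SD is the
training-score standard deviation stored in the model and reused unchanged
on any cohort; the map is strictly increasing, so AUC is invariant. The
discrimination slope (DS) is the mean risk probability in progressors minus
non-progressors, and IDI is reported as the percentage improvement in DS
over the reference model. The absolute IDI equals the continuous net
reclassification improvement integrated over all probability cut-offs, and
the package carries a numerical check of that identity.

One honest caveat: with ±1 labels the score mean sits near `2·prevalence − 1`
(about −0.46 at 27% prevalence), and the conversion above does not re-centre.
When the inner cross-validation settles on a large λ the score spread is
small relative to that offset, all probabilities land deep in one tail, and
absolute DS values become tiny. Rankings (AUC, DeLong) are unaffected; DS
and IDI magnitudes from heavily shrunk synthetic models should not be read
as clinically meaningful.

## The synthetic world

`synthetic_config()` defaults describe one fixed, documented world: 543
samples with exactly 146 progressors; 26 targeted plus 542 untargeted
features; seven planted markers whose per-SD log odds ratios enter the
outcome's logistic linear predictor directly (OR 2.18, 2.05, 1.86, 1.57,
0.82, 0.62, 0.55), with a 0.7 correlation between the glucose-like and
mannose-like features; null features in equicorrelated blocks (size 8,
ρ = 0.3 — untargeted metabolomics is block-correlated through lipid classes
and co-regulated pathways, and the source reports no usable correlation
matrix, so this is a stand-in); clinical covariates drawn per-covariate
class-conditionally from published group means and SEMs (SD = SEM·√n),
including the published missingness of family history, activity and
medication; and 5% missing-completely-at-random feature cells (a typical
below-detection share for untargeted panels; the mechanism is MCAR by design
decision, the rate is a package default). The progressor count is hit
*exactly* for every seed: the count is a non-decreasing step function of the
logistic intercept, and the generator takes the bisection's closed-form
limit (an order statistic of `logit(U_i) − LP_i`).

What the generator deliberately does **not** emulate — and therefore what a
green test does not establish:

* **Marginal effect sizes.** Planted values are *conditional* coefficients.
  Because the logistic link is non-collapsible, the *marginal* per-SD odds
  ratios realised in a multi-marker cohort are attenuated (by roughly
  `1/sqrt(1 + 0.35·σ²_rest)` ≈ 0.7 here, except where the glucose–mannose
  correlation adds back). Parameter-recovery checks therefore fit the
  generating (joint or single-marker) model; the univariate screen is
  expected to show attenuated marginals.
* **A realistically rich metabolome.** Only seven features carry signal; the
  remaining 561 are exchangeable noise. A whole-profile ridge model in this
  world therefore performs clearly below an oracle fit on the seven markers
  (the noise dimensions dilute it), whereas a real metabolome with dozens of
  correlated informative features supports a much stronger whole-profile
  model. The whole-profile-beats-clinical ordering reported for real data is
  *not* reproduced here.
* **Covariate dependence.** Clinical covariates are independent given the
  class (that is what a per-covariate class-conditional model means), which
  makes their joint separation — and hence the clinical-only reference
  model — *stronger* than in real data, where BMI, waist, insulin and blood
  pressure are mutually correlated. Combined with the attenuation above and
  the variance added by minimum-imputing MCAR cells, the greedy-selected
  metabolome model beats the clinical reference only in a cohort-dependent
  fraction of repetition comparisons, far from always. The corresponding
  acceptance check is left red — its failure message prints the measured
  medians — rather than re-tuned to pass.
* No batch or drift effects, no skewed intensity distributions (features are
  Gaussian on a per-feature affine scale shared between training and
  validation cohorts), no informative missingness.

## Numerical choices

* Eigenvalues of Gram/cross-product matrices are clipped at zero before the
  ridge path is evaluated; leverages `H_ii ≥ 1 − 1e-10` raise an error
  advising a larger λ.
* λ grid default: powers of two from 2⁻¹⁵ to 2¹⁵; inner-CV AUC ties resolve
  to the smallest λ; the modal λ of a repetition resolves ties the same way.
* Greedy candidates whose addition would drive a leverage to 1 are treated
  as inadmissible (the naive algorithm would fail on them).
* Pooled out-of-fold ROC curves carry a small, well-known pessimistic bias
  on null data (fold-level intercepts anti-correlate with held-out class
  composition), and the cross-validated null AUC of a single cohort scatters
  around 0.5 with SD ≈ 0.04 across cohorts; the null-calibration band of
  [0.45, 0.55] absorbs both.
* Sample standard deviations use the n−1 denominator throughout; features
  are imputed (per-feature minimum) before standardisation.
* The pipeline configuration format is JSON (no YAML parser is assumed);
  CLI flags override file values.

## Runtime scaling in the test suite

The acceptance checks keep the stated cohort dimensions (543×568), effect
sizes, repetition counts (20) and cohort count (10), but run the nested
cross-validation with 5×5 folds instead of 10×10 so the whole suite fits a
CPU budget of minutes rather than hours. Halving fold counts shrinks
training sets by ~11% and slightly disfavours the high-dimensional models;
it does not change any conclusion reported above.

## Known limitations

* DS/IDI magnitudes under heavy shrinkage (see above).
* The q-value plug-in uses a single fixed λ = 0.5 rather than a smoother; on
  very sparse alternatives it can be mildly conservative relative to the
  spline estimator.
* `sweep_panel_size` repeats greedy selection inside every training fold but
  evaluates all panel sizes along one greedy path per fold (the path prefix
  property of forward selection), not an independent search per size.
* External transfer assumes the validation platform measures the panel
  features under the same names; no cross-platform calibration is attempted.
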