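---
title: "Methods: inferring smoking habits and history from blood methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring smoking habits and history from blood methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesig)
```

## The problem

Tobacco smoking leaves a reproducible imprint on blood DNA methylation:
a small number of CpG sites (most prominently in *AHRR*, *F2RL3*, *GFI1*
and *MYO1G*) are strongly hypomethylated in current smokers, partially
revert after cessation, and scale with cumulative dose. `smokesig`
implements a complete pipeline for turning that imprint into validated
classifiers of smoking habit (current / former / never), cessation time and
pack-years, using only a finite marker panel — the setting relevant to
epidemiology (where questionnaires misreport) and forensics (where only a
blood trace is available).

The pipeline stages mirror how such classifiers are built in practice:

1. **Ascertainment** (`filter_candidates()`): candidate CpGs are taken from
   tabulated EWAS evidence and kept only when reported by at least two
   studies, with at least a 0.10 absolute beta difference between current
   and never/non-smokers in at least one study, and with a consistent
   direction everywhere. A zero difference has no direction and fails the
   consistency criterion by definition; the 0.10 bound is inclusive.
2. **Participant QC** (`apply_exclusions()`): participants are dropped for
   missing smoking status, then missing betas at the candidate CpGs, then
   any beta outside mean ± 4 SD per CpG.
3. **Marker selection** (`backward_eliminate()` + `chisq_stop()`): starting
   from the full candidate panel, the binary current-vs-non-smoker logit
   model is refit at each step and the marker with the smallest |z| =
   |coefficient| / SE is removed; the apparent AUC of each reduced model
   gives the cumulative AUC profile, and consecutive models are compared
   with a likelihood-ratio chi-squared test. Selection stops at the set in
   place just before the first significant removal.
4. **Model suite** (`build_*_model()`): binary, three-category multinomial,
   cessation-horizon, pack-year and five-category life-time models on the
   selected panel.
5. **Internal validation** (`kfold_cv()`, `bootstrap_optimism()`): fivefold
   cross-validation and bootstrap optimism correction of the apparent AUC.
6. **Comparisons and applications**: the plasma-cotinine 50 ng/mL cut-off
   (`cotinine_classify()`, `concordance_partition()`) and application of the
   frozen adult model to child cohorts (`children_application()`).

## Models and statistics

All classifiers are logit models. The binary models are maximum-likelihood
binomial GLMs; the three- and five-category models are baseline-category
multinomial logits with `never` (respectively category 1) as reference.
Predicted probabilities are the inverse logit (binary) or softmax
(multinomial); classification uses a strict `probability > threshold` rule
for binary models and the row argmax for multinomial ones.

The marker-elimination z-statistic is the Wald ratio coefficient/SE of each
marker's own coefficient; covariates (age, sex, cell proportions), when
included, are never elimination candidates. The stopping test is the
likelihood-ratio test between consecutive models (twice the log-likelihood
difference against a chi-squared law with the parameter-count difference as
degrees of freedom); for nested GLMs this is the standard deviance
comparison. The significance level defaults to `alpha = 0.05` and is
exposed in the pipeline configuration, since no canonical value exists for
this stopping rule.

AUC is computed as the Mann–Whitney statistic via mid-ranks — the
probability that a random positive outscores a random negative, with ties
half-credited — which is exactly equivalent to pair counting and is checked
against an independent ROC implementation in the tests. Accuracy intervals
are exact Clopper–Pearson binomial CIs.

Decision thresholds: 0.5 for the binary smoker and pack-year models
(strictly greater than), and the fixed constants 0.8733 / 0.7650 / 0.6397
for the cessation horizons 5 / 10 / 15 years. These three constants are
treated as given design constants of the published cessation models; their
derivation is not documented, so they are overridable per call but never
re-derived.

Boundary conventions differ deliberately between codings: the standalone
dichotomizations are inclusive at the cutoff (cessation ≥ horizon codes 1,
pack-years ≥ cutoff codes 1), whereas the five-category coding assigns
former smokers with cessation ≤ 10 years to category 3 and > 10 years to
category 2. Both are implemented exactly as defined and documented in the
respective functions.

## Internal validation

Fivefold cross-validation partitions the cohort into five equal
(within one) subsets without stratification by default — matching a plain
random split — with a `stratified` flag available; partitions whose
training folds miss a class are re-randomized up to 100 times and then
rejected.

Bootstrap optimism: for each replicate, a sample of size n is drawn with
replacement, the model refit, and its AUC measured on the replicate
(bootstrap-apparent) and on the original cohort (bootstrap-test). The mean
difference estimates the optimism, and the adjusted AUC is the apparent AUC
minus it. Replicate streams are seeded as `seed + b`, so reducing the
replicate count for quick runs never changes the replicates that remain.
The default in `run_pipeline()` is B = 200; fully stable optimism estimates
conventionally use B = 1000.

## The synthetic cohort generator

Restricted cohort data cannot ship with a package, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes, and
everything downstream is exercised against it:

* **Betas are logit-normal.** Each CpG has a never-smoker baseline
  `m0`; the group target mean is set *on the beta scale* as
  `m0 + delta * g(PY)` for current smokers and
  `m0 + delta * g(PY) * exp(-cessation / tau)` for former smokers, then
  mapped through the logit, perturbed with Gaussian noise
  (`noise_sd_logit`), and mapped back, so betas always land in [0, 1]. We
  set the target mean directly on the beta scale (rather than converting
  `delta` to a logit shift via the local derivative at the baseline)
  because it keeps the generative contract exact: the pre-noise
  current-vs-never difference *equals* `delta * g(PY)`, the same scale on
  which the 0.10 ascertainment criterion is expressed. The logit-normal
  mean is slightly shrunk toward 0.5 relative to the pre-noise mean; the
  tests quantify this against a Monte-Carlo oracle.
* **Dose response.** `g(PY) = PY / (PY + 10)`, a saturating form: no
  canonical dose-response curve exists for methylation, and saturation
  matches the observation that heavy smokers' shifts plateau. Pack-years
  and cessation times follow from simulated ages, start/stop ages and
  cigarettes/day; the derived quantities use the exact defining formulas
  (`compute_pack_years()`, `compute_cessation()`).
* **Noise level.** The default `noise_sd_logit = 0.5` was chosen so that
  the strongest default-panel marker (shift −0.24 at baseline 0.80) alone
  discriminates current smokers at an AUC near 0.88 — the level reported
  for the best single smoking CpG in whole blood — making multi-marker
  model AUCs land in the realistic low-0.9 range rather than at 1.0.
* **Effect sizes.** Published per-CpG effect sizes are plotted rather than
  tabulated in the source literature, so the default panel spans shifts
  −0.24…−0.10 (all hypomethylation, as observed for the strong smoking
  CpGs), with the 0.10 floor matching the ascertainment criterion.
* **Class mix and size.** Defaults: n = 3764 (the model-building set size)
  and current/former/never proportions 364/1332/1243 of 2939 (the
  three-category subset).
* **Cotinine and misreporting.** Plasma cotinine is log-normal with median
  200 ng/mL in true smokers and 2 ng/mL otherwise (sdlog 0.8), placing
  ~96% of true smokers above the 50 ng/mL cut-off and essentially all
  non-smokers below it. A 5% misreporting fraction turns true current
  smokers into questionnaire "never" smokers while leaving their cotinine
  and methylation smoker-like — emulating the imperfect sensitivity of
  self-report.
* **Children.** `generate_child_cohort()` produces non-smoking children
  whose methylation carries an attenuated maternal-smoking shift
  (defaults: 50% of the adult shift under sustained maternal smoking, 20%
  when the mother stopped on learning of the pregnancy, 0 for passive
  exposure) plus an optional additive logit offset for cord-blood tissue.
  The cord-blood offset stands in for the developmental and
  cell-composition differences that make adult models misfire on newborns.

What the generator does **not** emulate: array probe chemistry (detection
p-values, intensities), batch and plate effects, genetic effects on
methylation, correlated CpGs within a region, and cell-composition shifts
caused by smoking itself. Passing tests therefore demonstrate that the
statistical machinery is correct under the assumed generative structure,
not that the published accuracies transfer to any particular real cohort.

## Numerical choices and degenerate inputs

* GLM convergence: tolerance 1e-10 on the deviance, 100 iterations;
  multinomial fits use a relative tolerance of 1e-12.
* Separation is flagged when any |coefficient| exceeds 15 and reported as a
  warning with `separation = TRUE` on the fit, never silently. On
  beta-scale predictors (range ≤ 1) genuinely strong effects can produce
  large, finite slopes, so the flag is conservative: it marks fits to
  inspect, not necessarily failures.
* Ties in |z| during elimination are broken lexicographically by marker id,
  making the elimination order a pure function of the data.
* Rank-deficient designs (constant or duplicated CpG columns) are an error
  at fit time and surface from inside the elimination loop with the marker
  set that caused them.
* Betas are clipped to [1e-6, 1 − 1e-6] after logit-normal sampling.
* Metrics with empty denominators (sensitivity with no positives, AUC with
  one class, empty calibration bins) are returned as `NaN` with an
  `undefined` flag rather than dropped.
* An LRT between identical parameter counts has df = 0 and p = 1 by
  convention.

## Problem sizes used in the test suite

The suite exercises the recovery study at the full model-building scale
(n = 3764, 20 candidates, 20 seeds) and uses smaller cohorts
(n = 200–2500) for module-level properties; bootstrap behaviour is checked
at B = 200 (overfitting and large-sample regimes) with B = 1000 reserved
for full analyses. These sizes were chosen to make the stochastic
properties sharp (multiple seeds per claim) while keeping a full test run
under a minute on one core.

## Known limitations

* The three cessation thresholds are constants, not re-estimated; applying
  them to cohorts with very different cessation-time distributions will
  shift the sensitivity/specificity balance.
* The multinomial per-category specificity is defined from the argmax
  confusion (one-vs-rest); probability-thresholded per-class calls are not
  implemented.
* Optimism correction is implemented for the binary AUC; per-category
  optimism for multinomial models can be obtained by running the binary
  machinery on each one-vs-rest outcome.
* The generator's CpGs are conditionally independent given smoking status;
  real smoking CpGs within a locus are correlated, which mainly affects
  how much unique signal each extra marker adds.
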