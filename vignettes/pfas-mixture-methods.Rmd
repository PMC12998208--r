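---
title: "Methods: survey-weighted PFAS mixture analysis of cardiometabolic risk"
author: "pfasmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-weighted PFAS mixture analysis of cardiometabolic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package estimates

`pfasmix` estimates the joint association between a mixture of five
plasma PFAS (PFOA, PFOS, PFHxS, PFDA, PFNA) and cardiometabolic health
in complex-survey data. Three outcome families are supported:

* **Metabolic syndrome (MetS)** — a binary classification requiring at
  least three of five clinical criteria; modelled with modified
  Poisson regression (log link on a binary outcome with
  robust/replicate variance), so the reported quantity is a
  *prevalence ratio* (PR), not an odds ratio.
* **Cardiometabolic risk score (CMRS)** — a continuous severity score
  built from age- and sex-standardized residual Z-scores of five risk
  factors; modelled on its own scale, reported as a mean difference.
* **Individual risk factors (CMRFs)** — waist circumference, TG, HDL,
  SBP, DBP, HbA1c (and non-fasting glucose as an auxiliary outcome);
  log2-transformed before modelling and reported as the percent
  difference $(2^\beta - 1)\cdot 100$.

The mixture estimand comes from **quantile g-computation**: each
exposure is recoded to quartile scores $0\ldots 3$, the outcome is
regressed on all quantized exposures plus covariates, and the joint
effect is

$$\Psi = \sum_j \beta_j,$$

the effect of a simultaneous one-quartile increase in every exposure.
Coefficient shares within each sign give the positive and negative
**direction weights**, each set summing to 1. Single-pollutant models
(one log2 exposure at a time, "per two-fold increase") and a summed
∑5PFAS model complement the mixture model.

## Estimator variant

This package implements the *conditional, sum-of-coefficients*
("noboot"-style) quantile g-computation estimator for both the
gaussian and the log-link family. For the log link, $e^\Psi$ is
therefore a conditional PR; the marginalized g-computation variant
(standardizing over the covariate distribution) is out of scope, and
the choice is recorded in each result bundle's metadata. For a linear
link the two variants coincide.

# The synthetic cohort generator

Real national health-measures microdata are access-restricted, so the
package ships a generator whose defaults encode the study conditions
and whose ground truth is known, making every downstream stage
testable end to end.

**Exposures.** PFAS are drawn from a Gaussian copula with lognormal
marginals. The rank-correlation target is converted to the Pearson
correlation of the underlying normals by
$\rho_P = 2\sin(\pi\rho_S/6)$, which is exact for continuous
marginals, so empirical Spearman matrices converge to the target. The
copula operates *within sex*; because males carry higher geometric
means on every analyte (e.g. PFOS 5.2 vs 3.2 µg/L, PFHxS 1.6 vs 0.8
µg/L), the pooled rank correlations sit slightly above the within-sex
target — a feature of the emulated data, and the reason the fidelity
tests check the within-sex matrices. Default GSDs (1.7–2.2) and LODs
give >95% detection for four analytes and ~82% detection for PFDA,
whose LOD (0.105 µg/L) sits near the 18th percentile of its
distribution.

**Outcomes.** Each continuous risk factor is generated on the log2
scale as a linear model: sex-specific baseline, a linear age slope,
optional lifestyle-covariate effects, a shared standard-normal
"metabolic risk" factor that correlates the risk factors within a
person (loading 0.55 of the log2 SD, negative for the protective
HDL), an independent residual, and the ground-truth term
$\Psi_o \cdot \sum_j w_j q_{ij}$, where $q_{ij}$ are the quartile
scores of the generated concentrations and $w_j$ are configured
shares summing to 1. Because generation and estimation quantize the
same way, the quantile-g-computation estimand equals the configured
$\Psi_o$ exactly, which is what the parameter-recovery and type-I
error tests exploit.

**MetS is emergent, not drawn.** MetS status comes only from running
the classifier on the generated measurements and flags. Medication
(20%/21%/7% for lipid/BP/diabetes) and prior-diagnosis flags
(14%/5% hypertension/T2D) are drawn independently at their configured
prevalences. Because the flags are independent of the measurements —
whereas in real data medicated people are concentrated in the upper
measurement tails — baseline means taken directly from a survey
descriptive table would overshoot the target prevalence. The default
means are therefore calibrated once (risk-raising means scaled by
0.935, HDL by 1.065, with the original survey-table SDs retained) so
the emergent prevalence lands near 27%; the calibrated defaults are
frozen in `default_cmrf_params()`.

**Survey design.** A single stratum of 16 equal-probability
collection-site clusters, main weights lognormal with CV 0.3.
Replicate weights use the Rao–Wu–Yue rescaling bootstrap: each
replicate resamples $S-1$ sites with replacement and multiplies the
weight by $m_s\,S/(S-1)$ ($m_s$ = times site $s$ was drawn), so
replicate totals match the main total in expectation. The variance
rule is the mean squared deviation of replicate estimates about the
full-sample estimate, $\widehat{V} = (c/B)\sum_b(\theta_b -
\hat\theta)^2$ with scale $c = 1$ (no Fay factor) — both $B$ and $c$
are configurable because the emulated survey programme does not
publish them.

**What the generator does not emulate.** Multistage sampling frames,
nonresponse adjustment and calibration, cycle-specific LODs,
measurement error, real missingness patterns (including the ~25%
missing physical-activity subsample), and medication use conditional
on the underlying measurement. Passing tests therefore demonstrate
the estimators' internal validity under a known, well-behaved data
generating process — not robustness to every pathology of real
survey data.

# Exposure processing

1. **Retention rule:** analytes detected in at least 70% of samples
   are retained; the boundary is inclusive (exactly 70.0% is kept).
2. **Left-censored lognormal MLE:** detected values contribute the
   lognormal density and non-detects the CDF at their (possibly
   per-record) LOD. The fit maximizes the likelihood in
   $(\mu, \log\sigma)$ with BFGS (relative tolerance $10^{-12}$),
   initialized at the detected-sample moments; with zero non-detects
   it reduces to the closed-form MLE (mean and population SD of the
   logs). At least 10 detected values are required, and zero
   log-variance input is rejected rather than fitted. The estimator is
   censored maximum likelihood, not LOD/√2 substitution; an
   independent censored-MLE implementation (`fitdistrplus`) serves as
   a cross-check in the test suite.
3. **Single "fill-in" imputation:** each non-detect is replaced by one
   inverse-CDF draw from the fitted lognormal truncated to (0, LOD).
   Detected values are never altered (the tests assert bitwise
   equality). Each analyte uses its own deterministic sub-stream of
   the imputation seed, recorded in the provenance sidecar, so adding
   or dropping an analyte does not perturb the others' draws. The
   fill-in distribution is estimated on the pooled sample (cycles are
   not distinguished); per-record LOD columns support cycle-specific
   limits if supplied.
4. **Transforms:** per-analyte log2 concentrations for modelling;
   ∑5PFAS summed on the original µg/L scale (after imputation) and
   log2-transformed only when entering a model.

# Outcome derivation

**MetS criteria** (SI units; inclusive thresholds unless noted):
waist circumference ≥ 102/88 cm (male/female), lowered to 90/80 cm
for Asian ethnicity; TG ≥ 1.7 mmol/L or lipid medication; HDL < 1.0
(male) / 1.3 (female) mmol/L — strict inequality — or lipid
medication; SBP ≥ 130 and/or DBP ≥ 85 mmHg, or antihypertensive
medication, or prior hypertension diagnosis; HbA1c ≥ 5.7%, or
diabetes medication, or prior T2D diagnosis. MetS = at least 3 of 5.
HbA1c (percent scale; the registry stores thresholds in a versioned
CSV so guideline variants can be added) substitutes fasting glucose
because the emulated surveys drew non-fasting samples. Non-fasting
glucose (threshold 5.6 mmol/L) is available as an *auxiliary*
glycemia criterion for sensitivity checks only — it is never a CMRS
component. Records with any missing classifier input are rejected,
not silently classified: complete-case handling happens upstream.

**CMRS.** Each of WC, HbA1c, TG, HDL, SBP, DBP is standardized as the
residual from a linear regression on age (linear term) and sex,
scaled to weighted SD 1. Standardization is survey-weighted by
default (with an unweighted switch) and computed on the analytic
sample at hand. Then

$$\mathrm{zMAP} = z_{DBP} + \tfrac13(z_{SBP} - z_{DBP}), \qquad
\mathrm{CMRS} = \frac{z_{WC} + z_{HbA1c} + z_{TG} - z_{HDL} +
\mathrm{zMAP}}{\sqrt 5}.$$

CMRS is built from *untransformed* risk factors; the log2 transform
applies only when a risk factor is itself the model outcome. Under
independent standard-normal inputs, $\mathrm{Var(zMAP)} = 5/9$ and
$\mathrm{Var(CMRS)} = 41/45 \approx 0.9111$ — the test suite verifies
the Monte-Carlo variance against this closed form.

# Estimation engines

`fit_weighted_glm()` fits by IRLS (deviance tolerance $10^{-8}$,
maximum 100 iterations) with the main weights, then refits once per
replicate weight vector; gaussian refits use a direct weighted
least-squares solve and log-link refits warm-start from the
full-sample coefficients. Confidence intervals are Wald on the link
scale with the normal 0.975 quantile; no degrees-of-freedom
correction is applied. With no replicate weights (B = 0) the
modified Poisson estimator falls back to an HC0 sandwich variance so
the estimator remains usable outside survey contexts; when B ≥ 1 the
replicate variance *replaces* the sandwich. Fitted probabilities
above 1 under the log link trigger a logged warning, never silent
truncation. Listwise deletion is applied (and counted) at fit time,
though the pipeline enforces complete cases upstream; rank-deficient
model matrices are an error naming the collinear terms.

`fit_qgcomp()` quantizes with empirical quartile cutpoints (type-7
quantiles); ties at a cutpoint fall in the lower bin (left-open
intervals), which makes scores — and hence $\Psi$ and the weights —
invariant to any strictly monotone transform of a raw exposure.
Cutpoints are computed unweighted on the analytic sample of the fit
and held fixed across replicate refits, so replicate variation
reflects estimation, not re-binning; stratified fits recompute
cutpoints within stratum. No exposure interactions or nonlinear
quantile terms are fitted.

# The model battery

For each stratum (total, males, females) × outcome (MetS, CMRS, WC,
TG, HDL, SBP, DBP, HbA1c), the battery fits 1 mixture model + 5
single-analyte models + 1 ∑5PFAS model = 7 rows, giving 3 × 8 × 7 =
168 primary rows. Adjustment sets: base covariates (race/ethnicity,
education, smoking, marital status, country of birth, physical
activity, fish/shellfish consumption, survey cycle) plus age; sex is
added only in total-population models; female models add parity; CMRS
models drop age and sex in every stratum (already standardized for).
Pregnant participants and type-1 diabetics are always excluded. For
the six medication-linked risk factors the *primary* variant excludes
users of the matched medication class (lipid-lowering for TG/HDL,
antihypertensive for SBP/DBP, diabetes medication for HbA1c/glucose),
and an everyone-included complement is always emitted as a named
sensitivity variant; the CMRS conversely gains an
all-medication-excluded sensitivity variant. Exclusion audit counts
are incremental (each rule counts only rows not already removed), so
they sum exactly to the rows dropped. No multiplicity adjustment is
applied anywhere; downstream interpretation should weigh direction,
magnitude and consistency rather than significance flags.

# Numerical and reproducibility choices

* One master seed drives generation, imputation and replicate
  construction through fixed integer sub-streams (a Lehmer-style
  derivation keeping every derived seed below $2^{31}$); a full
  `simulate → report` run is byte-identical under a repeated seed.
* The censored MLE optimizes over $\log\sigma$ to keep the SD
  positive; imputed draws are clamped a relative $10^{-12}$ below the
  LOD to protect the truncation contract against quantile-function
  rounding.
* Correlation targets are validated for symmetry, unit diagonal and
  positive semidefiniteness *after* the copula conversion; the
  factorization uses an eigendecomposition with negative eigenvalues
  clipped at zero, so exactly-singular targets are accepted, non-PSD
  ones rejected with the offending eigenvalue.
* Quantile bins on heavily tied data can collapse; constant analytes
  are an explicit error rather than a silent single-bin fit.

## Problem sizes used by the test suite

Marginal-fidelity checks run at n = 20,000–50,000; parameter-recovery
and type-I-error studies use 200 replications of n = 2,000 cohorts
with B = 200 replicate weights; replicate-variance validity uses 200
cohorts of n = 1,000 with B = 500; the modified Poisson recovery uses
n = 5,000; the CMRS variance check uses 10^6 Monte-Carlo draws; the
end-to-end determinism check runs the full pipeline twice at n = 600,
B = 30. These sizes keep the whole suite within a coffee break while
leaving Monte-Carlo error comfortably inside each test's band.

# Known limitations

* The conditional qgcomp variant only; marginalized PRs for common
  binary outcomes will differ from conditional ones.
* Replicate-weight variance assumes the single-stratum cluster
  bootstrap design the generator produces; Taylor linearization and
  design strata are not implemented.
* The CMRS has no standard construction across the literature; this
  package fixes the five-component, equal-weight, √5-scaled version
  and treats alternatives as out of scope.
* Single imputation below the LOD understates between-imputation
  uncertainty by construction; with ≤18% non-detects on one analyte
  this is a second-order effect here, but heavier censoring would
  warrant multiple imputation.
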