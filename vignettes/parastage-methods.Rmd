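---
title: "Methods: stage-structured parasitism risk under imputed host stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-structured parasitism risk under imputed host stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parastage)
```

This vignette is the package's own account of its statistical
machinery: the models, the assumptions they lean on, the numerical
choices, and the places where the design was genuinely open and a
choice had to be made.

## 1. The experiment and its missing-data structure

One host per replicate per diet treatment is exposed to a single mated
female parasitoid for 24 hours on each day of host development (ages 5
to 60 days). The host's developmental stage at exposure — larval
instars L1–L4, pupa P, adult A — is observed *only when the host is
parasitized*: paralysis freezes development, and dissection recovers
one molted head capsule per completed larval molt
(`stage_from_head_capsules()`). Unparasitized hosts develop on; their
stage on the exposure day is gone.

The missingness is therefore structural, not accidental, and it is
informative in the aggregate: the probability a host occupies a given
stage on a given day depends on its diet. The remedy is a
*missing-category imputation*: empirical age-by-stage probability
tables per diet, estimated from reference rearing data
(`estimate_stage_distribution()`), from which unobserved stages are
sampled (`impute_stages()`).

Two conditioning caveats are worth stating plainly:

* The tables condition on a host being present (alive, unemerged) at
  that age in the reference data, not on it being unparasitized. A
  host's survival to exposure day is taken as exchangeable with the
  reference population's.
* Dead hosts and adult hosts that emerged from their seed before
  exposure are excluded from the hazard analysis entirely — they were
  never at risk. The generator records both flags (`host_died`,
  `host_emerged`).

## 2. The hazard model

Within each stage s, with host age at exposure as the time axis and
parasitism as the event,

$$h_i(t) = h_{0s}(t)\,\exp(\lambda_{90}\,[Q_i{=}90] + \lambda_{95}\,[Q_i{=}95]),$$

the 100% diet being the reference. Each host contributes exactly one
row: its single 24-h exposure, treated as a point event/censoring at
its age in days. The alternative — modelling the 24-h window as an
interval — was considered and rejected as over-modelling a design in
which every host has the same one-day window.

Ages are integers, so ties are massive (often hundreds of events per
day). The partial likelihood implements both the Efron and Breslow tie
corrections; Efron is the default, matching the default of the
standard survival software this analysis descends from. The two are
asserted equal on tie-free data in the tests.

Numerical details:

* Newton–Raphson with step-halving; the step is halved until the
  partial likelihood does not decrease.
* Convergence when the score's infinity norm falls below
  `1e-8 × max(1, |loglik|)`. The scaling matters: with thousands of
  rows the score cannot be accumulated in double precision below the
  float noise of the log-likelihood's own scale, and an absolute 1e-8
  would spuriously flag perfectly converged fits (the estimates agree
  with `survival::coxph` to ~9 digits in the cross-check tests).
* Monotone likelihood (separation — e.g. every event in one arm) is
  detected as any |λ| exceeding 10 and flagged `monotone`;
  such fits count as failures inside the resampling loops.
* A stage whose subset has no events, or only one treatment, is
  reported as an explicit skipped-stage marker, not an error.

L1 is excluded from hazard analyses by default: first-instar
parasitism is a rare and uninformative event, and a stage with
(nearly) no events cannot support the model.

## 3. Imputation bootstrap and the treatment-agnostic null

The reported coefficient per stage × contrast is the *mean of B
re-imputation replicates*: impute unobserved stages, refit all stage
models, repeat. Nothing else is resampled — not the data rows, not the
observed stages. The spread of the replicate coefficients reflects
imputation uncertainty only; that is the deliberate, literal design of
this inference, and the reported λ is the imputation-averaged
estimate rather than any single completion's.

The null distribution severs the treatment–risk link while preserving
everything else: each replicate (i) permutes the diet labels across
hosts, preserving group sizes; (ii) re-draws *every* host's stage —
parasitized hosts included — from the table cell of its permuted label
and age; (iii) refits. Significance is the two-sided percentile
position of the observed mean within the null replicates, with the
half-count convention for ties and a floor of 1/B (no zero p-values),
Bonferroni-adjusted across the stage × contrast family.

Two genuinely open points and the choices made:

* "Resampling individuals without regard to treatment" is ambiguous
  between a label permutation and with-replacement pooled resampling.
  The permutation is the default (it preserves group sizes exactly, a
  property the tests assert); a pooled variant is available via
  `build_null_distribution(..., scheme = "pooled")`. Neither is
  asserted to be the historical scheme.
* In the null, observed stages of parasitized hosts *are* overwritten
  — the null is over stage assignment as well as labels. This is the
  literal reading of re-assigning "all individuals".

The production default for B is 100,000; tests and the bundled
profiles use B = 200, at which the Monte-Carlo standard error of a
percentile p near 0.05 is about $\sqrt{0.05\cdot 0.95/200} \approx 0.015$.

Calibration and power are checked by simulation in the test suite: at
2,016 exposures and B = 200, across 400 generated experiments with no
diet effect, the percentile test's rejection rate at nominal 0.05 must
land in 0.05 ± 0.02; and the rejection rate must be nondecreasing in a
configured effect size.

### Parameter recovery and the estimand

One test configures a true L4 log hazard ratio of −0.7 (90% vs 100%)
and requires the mean bootstrapped λ to land within 0.2 of it in at
least 80% of 25 runs. Designing that experiment forced a clarification
of *what the configured parameter is*. The generator's per-exposure
attack probabilities are discrete daily hazards; a proportional-hazards
effect is configured on the complementary-log-log scale,
$p_{90} = 1-(1-p_{100})^{e^{-0.7}}$. But the Cox partial likelihood
with the Efron correction estimates the continuous-time hazard ratio,
and when per-day event probabilities are large (the default L4 attack
success is 0.55) the tie approximation attenuates the estimate — an
estimator property, not a defect of the resampling pipeline. The
recovery experiment therefore uses moderate within-stage daily attack
probabilities (0.2 at the reference), a regime where the configured
coefficient is the estimand, and sizes the simulation so that roughly
5,000 hosts fall in the L4 analysis set. The study-scale defaults are
left untouched; they are the *conditions*, the recovery experiment is
an *instrument check*.

## 4. The synthetic experiment

The generator's defaults encode the study conditions:

| parameter | default | meaning |
|---|---|---|
| design | 54 × (5–60) × {90, 95, 100} | replicates × ages (days) × % flour |
| boundaries (100%) | 7, 11, 15, 21, 28 d | L1/L2, L2/L3, L3/L4, L4/P, P/A |
| delay 95% / 90% | ×1.014 / ×1.014·1.22 | 1.4% slower; a further 22% slower |
| size reduction 95% / 90% | 15% / 1−0.85·0.54 ≈ 54% | asymptotic biomass shrinkage (15%, then a further 46%) |
| transition noise | lognormal, sd 0.08 | shared per-host multiplier |
| attack success | 0.001, 0.05, 0.35, 0.55, 0.35, 0.08 | per stage L1…A, diet-independent |
| emergence success | 0, 0.7, 0.85, 0.9, 0.9, 0.8 | adult parasitoid per parasitized host |
| sex allocation | logistic in host age, midpoint 22 d | even allocation near 3 weeks |
| development time | male 12.5 d, female +1 d, Gamma noise | ~12–14 d window |
| tibia | saturating ramp, plateau 25 d, +0.05 mm female | mm |
| mass allometry | per-sex log-log slope ~3 | mg vs mm |

Individual variation in stage boundaries is one shared lognormal
multiplier per host applied to all boundaries — the simplest
positive-skew model that preserves boundary ordering exactly.
Quality-specific host mortality is unquantified in the source system
and defaults to zero, configurable per diet.

What the generator does *not* emulate — and hence what passing tests
cannot certify about real data: parasitoid behaviour and host choice;
egg-transfer and rearing mechanics; within-day timing of attack;
diet-dependent attack profiles (available via configuration but off by
default); any correlation between a host's development speed and its
attractiveness conditional on stage. The generator's exchangeability
under "no quality effect" settings is itself tested by permutation.

Determinism: all randomness flows through R's seeded generator with
hosts processed in fixed design order, so a configuration plus seed
reproduces byte-identical tables (asserted in the tests; the pipeline
writes per-stage substream seeds to its log).

## 5. The regression suite

Efficacy and life-history responses are compared across candidate
GLMs/GAMs ranked by AIC, or qAIC where a quasi-likelihood family
absorbs overdispersion:

* GLM fitting is iteratively reweighted least squares via `stats::glm`
  behind `glm_fit()`; the container adds the exact-likelihood twin's
  log-likelihood (for quasibinomial, the binomial log-likelihood at
  the same coefficients), the Pearson dispersion
  $\hat c = \chi^2_P/\mathrm{df}$, and the parameter count.
* qAIC uses $-2\ell/\hat c + 2(k+1)$, with $\hat c$ taken from the
  most complex candidate and applied to the whole set — the standard
  practice when the selection family is quasi.
* Superparasitized hosts (more than one egg) are excluded from
  life-history analyses with counts reported; efficacy analyses keep
  all rows.
* Post-hoc contrasts are Wald tests on the linear predictor with
  Bonferroni adjustment throughout. (A multivariate-t single-step
  correction would be tighter; Bonferroni was chosen for consistency
  with the smooth comparisons, and is the conservative end.)

### Penalized splines

Smooth terms `s(A)` and `s(A, by = F)` are cubic B-splines with a
second-order difference penalty:

* k = 10 basis functions by default on *equally spaced* knots over the
  covariate range, extended three knots beyond each end so the basis
  rows sum to one on the whole range. Uniform knots make the penalty
  null space exactly the linear functions (the Greville abscissae are
  linear in the coefficient index), so the infinite-penalty limit is
  exactly the least-squares line with edf 2 — a limit the tests pin at
  ±0.05. Quantile-spaced knots would trade that exactness for better
  behaviour under very uneven covariate designs; the target design's
  ages are uniform, so nothing is lost here.
* Each smooth block carries a sum-to-zero constraint (QR projection of
  the basis against its column sums) for identifiability against the
  intercept and by-factor main effects.
* Fitting is penalized IRLS; the smoothing parameter (one per smooth
  term, shared across its by-levels) minimizes the GCV score
  $n\,D/(n-\mathrm{edf})^2$ over a log grid — 14 points in
  $10^{-4..9}$ for one term, a 9 × 9 grid in $10^{-3..9}$ for two
  terms, a shared parameter beyond that. Effective degrees of freedom
  are the trace of the influence matrix.
* Gamma/inverse-link fits step-halve back toward the previous
  coefficients whenever a proposal leaves the family's domain.
* This machinery approximates, and is cross-checked in the tests
  against, an independent thin-plate-spline GAM implementation on a
  known-signal recovery task; exact equality with any particular
  smoother's AIC values is out of scope by design.

Pairwise smooth comparison (`compare_smooths()`) evaluates the
difference between two by-levels' fitted curves on a grid, *including*
their parametric offset (so a pure level shift is part of the
difference), with pointwise variance from the joint coefficient
covariance and a Bonferroni-widened interval when several level pairs
are compared.

## 6. Problem sizes

The bundled test and acceptance runs use deliberately scaled settings
chosen as the package's own test design: B = 200 resampling
replicates (production: 100,000), 400 calibration experiments of
2,016 exposures, a recovery experiment with ~5,000 L4 hosts, 50
selection-consistency simulations at n = 1,000, and reference tables
of 30–50 hosts per (diet, age) cell. The acceptance script runs the
full 9,072-exposure design end to end.

## 7. Known limitations

* The percentile test compares an imputation-*averaged* statistic with
  single-replicate null draws; with B large the observed statistic's
  imputation noise is averaged out while the null's is not, which can
  make the test mildly anti-conservative when imputation noise is a
  large share of the total (the calibration simulation bounds the
  effect under the study-like conditions tested).
* Efron/Breslow estimates attenuate toward zero at very large per-day
  event probabilities (see §3); stage-specific λ at the default L4
  attack rates should be read as Efron-scale effects, not
  complementary-log-log effects.
* The smoothing-parameter search is a coarse grid, not a
  REML/Newton optimization; smooth comparisons inherit pointwise, not
  simultaneous, coverage (Bonferroni across level pairs only).
* No time-varying covariates, stratified baselines, frailty terms, or
  parasitoid behavioural structure.
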