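---
title: "Modelling pressure-injury healing trajectories with piheal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pressure-injury healing trajectories with piheal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piheal)
```

## The problem

Home-visiting nurses managing pressure injuries (PIs) rarely have a wound
expert at hand. A decision-support system therefore needs a *fail-safe*: a
statistical prediction of how the wound severity should evolve under
appropriate care, so that an observed trajectory falling outside the
predicted range can trigger an actual expert consultation. `piheal`
implements the statistical core of such a system: a hierarchical Bayesian
regression (HBR) of changes in the DESIGN-R 2020 severity score, marginal
likelihood based predictor selection, and prediction-interval coverage
validation. It also implements the quantitative metrics used to evaluate an
expert-derived care-recommendation algorithm against a wound-expert's
judgment (agreement and improvement proportions, expected healing level).

## Severity score and coding

DESIGN-R 2020 scores a PI on seven subscales: Depth, Exudate (E), Size (S),
Inflammation/infection (I), Granulation (G), Necrotic tissue (N), Pocket
(P). The total severity score is the sum of the six non-depth subscales
(0–66, higher is worse). Each subscale's permissible values are partitioned
into a severe ("large", uppercase) and mild ("small", lowercase) class;
`binarize_subscale()` encodes a score as a mutually exclusive dummy pair,
with both dummies 0 exactly when the score is 0. Only the Exudate partition
(large = {6}, small = {1, 3}) is fixed by the modelling context; the other
partitions ship as an instrument-derived, overridable configuration table
(`designr_cutoffs()`) following the published uppercase/lowercase
convention.

## The hierarchical model

The modelled unit is the change between consecutive assessments of one
lesion $i$: $d_i(t,s) = y_{i,t+s} - y_{i,t}$, where $y_{it}$ is the total
score at day $t$ and $s$ is the gap (days) to the next assessment. No
transformation is applied (changes are frequently negative). The model is

$$d_i(t,s) = X_i(t,s)\,\beta_i + \epsilon_i(t,s), \qquad
\epsilon_i(t,s) \sim \mathrm{Normal}(0, \sigma^2),$$

with design row $X_i(t,s) = (1,\; s,\; [s^2],\; x_1(t), \dots, x_k(t))$ and
lesion-level coefficients

$$\beta_i \sim \mathrm{MultiNormal}(\mu,\; \Sigma_\mathrm{chol}
\Sigma_\mathrm{chol}^\top), \qquad
\Sigma_\mathrm{chol} = \mathrm{diag}(\zeta)\,\Omega_\mathrm{chol}.$$

$\mu$ carries the fixed effects, $\zeta \ge 0$ the between-lesion scales,
and $\Omega_\mathrm{chol}$ is the Cholesky factor of the coefficient
correlation matrix. Priors:

* $\sigma \sim \mathrm{Normal}^+(0, 100)$ — scale 100 score points, i.e.
  essentially uninformative for a 0–66 instrument;
* $\mu_\mathrm{intercept} \sim \mathrm{Normal}(0, 10)$, all other means
  $\sim \mathrm{Normal}(0, 1)$ (covariates enter in raw units — days,
  years, score points — so unit-scale priors encode "effects of at most a
  few score points per unit");
* each $\zeta \sim \mathrm{Student\text{-}t}^+(4, 0, 1)$;
* $\Omega_\mathrm{chol} \sim \mathrm{LKJ}(4)$, mildly favouring weak
  correlations.

The squared gap $s^2$ is a model-level flag rather than an ordinary
predictor because the mean vector comes in two documented layouts (with and
without $\mu_{\beta_{s^2}}$); the candidate machinery can still screen it
like any predictor.

All truncated densities carry their normalizing constants (the half-normal
and positive-t include the factor 2; the LKJ density is evaluated in
normalized form through its canonical-partial-correlation factorization).
This matters: bridge-sampling marginal likelihoods are meaningless if any
prior factor is unnormalized.

### Sampling

`sample_posterior()` runs a No-U-Turn sampler on the unconstrained
parameterization: log transforms for $\sigma$ and $\zeta$, the
stick-breaking partial-correlation transform for $\Omega_\mathrm{chol}$,
and a non-centered parameterization $\beta_i = \mu +
\mathrm{diag}(\zeta)\,\Omega_\mathrm{chol}\, z_i$ with standard-normal
$z_i$ — small-cohort hierarchical posteriors mix poorly when centered, and
the target density is unchanged. Warmup adapts the step size by dual
averaging (target acceptance 0.95: the half-t scale posteriors have funnel
geometry, and a conservative step size keeps divergences near zero) and a
diagonal mass matrix from the middle warmup window. The default `"desk"`
profile (4 chains × 2000 draws after 1000 warmup) is ample for cohorts of
a few dozen lesions; a `"replication"` profile (3 × 40,000 after 10,000) is
provided for strict replication of the original configuration. Convergence
is gated on the split Gelman–Rubin statistic ($\hat R < 1.1$ for every
parameter); divergent transitions are counted and reported. Runs are fully
reproducible from the seed.

## Evidence and predictor selection

Model evidence is estimated by Warp-III bridge sampling
(`log_marginal_likelihood()`): posterior draws are split in half, the
second half moment-matches an affine map to a standard-normal proposal, the
warped posterior is symmetrized by a sign-flip mixture, and the optimal
(Meng–Wong) bridge update is iterated to a relative tolerance of $10^{-10}$
(cap 1000 iterations; non-convergence is an error carrying the last two
iterates). The estimate is the mean of 5 repetitions, each with fresh
splits and proposal draws. Two models with equal prior probability are
compared by the posterior model probability
$\Pr(M_p) = \mathrm{e}^{\ell_p} / (\mathrm{e}^{\ell_p} + \mathrm{e}^{\ell_0})$,
computed stably in log space.

Selection (`select_final()`) mirrors the study procedure: the base model
uses the prediction gap only; every candidate predictor is screened
one-at-a-time against the base model and kept when its posterior model
probability strictly exceeds 0.95; all combinations of the kept predictors
are fitted and the highest-evidence combination becomes a fold candidate;
this is repeated on 5 random 80% lesion-level subsets of the training data
(sampling without replacement, seeded — folds never split a lesion's
records, since the lesion is the exchangeable unit); finally the distinct
fold candidates are re-evaluated on all training data and the best evidence
wins. Ties within the combined repetition SD resolve to the smaller model,
then lexicographically — reproducibility demands a documented tie-break.
Fits failing the $\hat R$ gate are excluded and reported.

## Prediction and the fail-safe statistic

`sequential_predict()` predicts each next assessment of a held-out lesion
from the preceding one: the covariates are built from the last observed
assessment and the interval for the next total is the last total plus the
predicted change. Three predictive modes are exposed:

* **population** (default): $\beta = \mu^{(g)}$ per posterior draw $g$ —
  the "between-lesion scales set to zero" rule for a lesion with no
  history;
* **pi_specific**: $\beta^{(g)} \sim \mathrm{MultiNormal}(\mu^{(g)},
  \Sigma^{(g)})$ — a fresh lesion exchangeable with the cohort;
* **posterior**: the lesion's own fitted $\beta_i$ draws (posterior
  updating on its accumulated changes), available for lesions in the
  fitted data.

Intervals are central empirical quantiles of the predictive draws
(`prediction_interval()`, default level 0.90), endpoints inclusive —
scores are integers and boundary ties occur. Totals are *not* clipped when
checking coverage: the raw score is compared with the raw interval.
`coverage_probability()` reports the fail-safe statistic per lesion and
pooled count-wise (sum of covered over sum of assessed).

## The synthetic cohort generator

No assessment data are deposited with the study, so `generate_cohort()`
simulates cohorts with the exact statistical structure the model assumes:
per-lesion coefficients drawn from $\mathrm{MultiNormal}(\mu, \Sigma)$,
successive changes from the Gaussian likelihood, covariates from
configured prevalences. Defaults emulate the published training cohort: 14
lesions, 2–4 assessments about 14.7 days apart (mean follow-up 29.4 days),
age 79.4 (SD 8.4) years, risk-factor and comorbidity prevalences at the
published cohort frequencies, and generating hyperparameters at the
published best-model posterior means with $\Omega = I$. The residual SD is
not published; the default $\sigma = 2$ score points is a realistic
assessment-to-assessment fluctuation for this instrument. Lesions are
simulated independently (the model indexes lesions, not patients; the
study gives no within-patient correlation to emulate).

Three consequences of the instrument are handled explicitly and counted:

* simulated totals are clipped into $[0, 66]$ (`clip_events` attribute);
* in integer mode, changes are rounded to whole points and each total is
  decomposed into permissible subscale values by exact enumeration of all
  subscale combinations, choosing the attainable sum closest to the target
  (always within one point) and breaking ties toward a configured
  proportional allocation — the model consumes totals and dummies, so any
  consistent, documented scheme suffices;
* a continuous mode (`integer_scores = FALSE`) skips rounding and
  decomposition for pure model checks.

What the generator does **not** emulate: care-intervention effects,
informative assessment timing, patient-level clustering of multiple
lesions, and measurement error in the subscales. Passing tests therefore
show that the pipeline is correct *under the model's own assumptions*, not
that the model describes any particular clinic's data.

### Calibration experiments

Calibration and recovery simulations use a separate documented truth,
`calibration_truth()`: a compact specification (intercept, prediction gap,
age) in which each coefficient contributes about one score point of
between-lesion dispersion against $\sigma = 2$. The reason is
identifiability, not convenience: in the full best-model structure the
lesion-constant covariates (age, baseline score, intercept) have random
effects that are collinear within a lesion, so a cohort of a few dozen
lesions cannot identify the 7×7 coefficient covariance and fixed-truth
predictive coverage stays conservative regardless of how well the
machinery works. Under the identified compact regime, pooled fresh-lesion
coverage of nominal 90% intervals sits within binomial error of 0.90
(about 0.91–0.94 across seeds, the residual excess being the usual
finite-sample conservatism of a posterior-averaged predictive). The
published posterior means, taken marginally with an identity correlation,
are *not* used as a calibration truth: they imply between-lesion change
SDs of 7–13 points, constant clipping, and explosive quadratic
extrapolation beyond the observed follow-up range — marginal posterior
means from a 42-record fit do not jointly define a realistic generating
process.

Problem sizes used by the packaged experiments: the acceptance script pools
3 replicates of (30 training + 30 held-out lesions, 3–6 assessments each,
2 chains × 1000 draws after 600 warmup) for the coverage check, fits the
7-coefficient best-model structure to a 14-lesion cohort at the desk
profile for the convergence gate, and checks the screening threshold
boundary algebraically. The test suite uses smaller cohorts and chain
lengths per check; all sizes are stated in the tests themselves.

## Study-appraisal metrics

For the expert-algorithm evaluation, ratings compare the high-expertise
algorithm with a base algorithm on a 0–4 scale per care field and
vignette. `agreement_proportion()` counts ratings in {0, 3, 4};
`improvement_proportion()` counts {3, 4} among {1, 2, 3, 4} and is `NULL`
for a field whose ratings are all 0 — such fields contribute neither
numerator nor denominator to pooled totals, the only reading consistent
with the published round totals. Pooling is count-wise, not a mean of
per-field fractions. The packaged ratings file is a synthetic
reconstruction: individual ratings were not published, so representative
values consistent with the published per-field class counts are shipped
(and reproduce the published totals exactly).

## Numerical choices and limitations

* Continuous predictors enter in raw units (days, years, score points),
  matching the scale of the published posterior summaries; standardization
  is deliberately not silently applied.
* The likelihood is continuous although observed changes are integers; at
  typical residual scales (≥ 2 points) the discretization is minor, and
  the generator's continuous mode exists precisely to separate this
  approximation from model checks.
* Bridge sampling warns when the posterior sample is small relative to the
  parameter dimension; evidence estimates on unconverged fits are refused
  by the $\hat R$ gate upstream.
* Ties in evidence comparisons, fold draws, and the train/test split (by
  follow-up length, longest to test) all have documented deterministic
  tie-breaks (smaller model, lexicographic lesion id).
* The combination search is exponential in the number of selected
  predictors and is capped (configurable, default 64 models).
* Lesions are modelled independently; a patient-level second hierarchy,
  ordinal likelihoods for integer changes, and care-recommendation rules
  are out of scope.
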