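---
title: "Methods: usability scoring and Bayesian indirect comparison of inhalers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: usability scoring and Bayesian indirect comparison of inhalers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gusnet` analyses device-usability studies built on the Global Usability
Score (GUS), a 0–50 composite computed from five questionnaire "boxes"
(preference at glance, nurse-measured critical issues, actuation attempts
and time to autonomy, and ten closed acceptance questions). Seven
dry-powder inhalers — Breezhaler, Diskus, Ellipta, Genuair, Nexthaler,
Spiromax, Turbohaler — are compared in an incomplete-block within-patient
design: each respondent tests only the 2–4 devices of their group, and a
Bayesian indirect-comparison model pools all within-respondent contrasts
into a single coherent ranking, separately for DPI-experienced and
DPI-naive cohorts.

The design shipped as `paper_design()` fixes three groups: Group 1
(n = 36; Breezhaler, Spiromax, Nexthaler, Ellipta), Group 2 (n = 37;
Breezhaler, Spiromax, Diskus, Turbohaler) and Group 3 (n = 30;
Breezhaler, Genuair), split 74 experienced / 29 naive. Breezhaler appears
in every group, so each stratum's evidence network is connected through
it; it is therefore also the model's reference device.

# The scoring engine

Scoring is driven entirely by a JSON configuration (`read_scheme()`), not
by hard-coded weights, because the validated instrument's item weights
are not publicly deposited. The shipped `default_scheme()` is a clearly
labelled synthetic placeholder that honours every structural constraint:
five boxes with maxima (10, 10, 10, 10, 10) summing to 50, categorical
preference items in box 1, count/time threshold rules in boxes 2–4, and
ten yes/no questions in box 5.

Numerical conventions:

* Threshold rules use half-open intervals `[lo, hi)`; a value exactly on
  a boundary belongs to the interval it opens. This makes boundary
  behaviour unambiguous.
* Measurement mappings must be monotone non-increasing — more attempts or
  more seconds can never score more points — and `validate_scheme()`
  rejects any scheme violating this, the 50-point total, or a box
  maximum inconsistent with its items.
* Missing answers raise errors and are never imputed: the questionnaire
  is administered under nurse supervision and arrives complete, so a
  missing item indicates a data-handling fault.

`inverse_questionnaire()` inverts the engine: for any attainable total it
reconstructs (by dynamic programming over the items' attainable point
sets, with a seeded choice among the many valid decompositions) an answer
set scoring exactly that total. The round trip `score(inverse(t)) = t`
over all attainable totals is the scoring module's end-to-end test.
Inversion requires integer item points; totals unattainable under a
scheme's granularity fall back to the nearest attainable value with a
warning.

# The indirect-comparison model

For one stratum, with `y_ik` the GUS total of respondent `i` on device
`k`:

```
y_ik = mu_i + delta_ik + eps_ik,   eps_ik ~ N(0, tau^2)
```

`mu_i` is a respondent-level intercept (the respondent's level on their
baseline device, defined as the first of their tested devices in
canonical alphabetical order), and `delta_i,base(i) = 0`.

* **Fixed effect (FE):** `delta_ik = d_k - d_base(i)` — every respondent
  expresses the same relative device effects `d` (with `d_ref = 0`).
* **Random effect (RE):** `delta_ik ~ N(d_k - d_base(i), sigma^2)`,
  independently across a respondent's contrasts; `sigma` is the
  between-respondent heterogeneity of the device effects.

Default priors are vague on the bounded 0–50 scale: `d_k ~ N(0, 100^2)`,
`mu_i ~ N(25, 100^2)`, `tau ~ U(0, 50)`, `sigma ~ U(0, 25)`.

## Why the contrasts are independent, not correlated at sigma^2/2

For contrast-level random effects in network meta-analysis one often
gives a multi-arm block the "consistency" covariance sigma^2/2 between
contrasts sharing a baseline. That construction is correct when each
contrast is an observed effect *estimate* with known sampling error. Here
it interacts fatally with the rest of the model. Writing
`w_ij = y_ij - y_i,base` for the observed contrasts, the sigma^2/2
structure implies

```
Var(w) = 2 tau^2 + sigma^2,    Cov(w_j, w_l) = tau^2 + sigma^2 / 2
```

so `Var(w) - 2 Cov(w) = 0` identically: the likelihood depends on
`(tau, sigma)` only through `2 tau^2 + sigma^2`, and the pair is
structurally unidentified — the posterior lies on a ridge, the
heterogeneity sd cannot collapse on homogeneous data, and the FE/RE DIC
comparison degenerates. (Equivalently: arm-level i.i.d. heterogeneity,
whose image on contrasts is exactly that covariance, is indistinguishable
from residual noise.) We verified this both analytically and by fitting
the correlated model with two independent MCMC implementations.

With independent contrasts the covariance becomes

```
Var(w) = 2 tau^2 + sigma^2,    Cov(w_j, w_l) = tau^2
```

which identifies both variance components through the multi-arm groups.
This matches the substantive definition of heterogeneity — each
respondent expresses their own *relative* effect `delta_i ~ N(d, sigma^2)`
— and restores the expected model-comparison behaviour.

## Sampler

The Gibbs sampler (C++, `src/sampler.cpp`) uses exact conjugate updates
throughout: normal draws for `mu_i`, `d_k` and the latent contrasts, and
truncated inverse-gamma draws for `tau^2` and `sigma^2` (a uniform prior
on an sd is an inverse-gamma kernel on the variance with shape reduced by
1/2; truncation is handled by rejection). Because `(tau, sigma)` moves
only slowly through the latent contrasts, each RE iteration ends with a
collapsed Metropolis refresh of `(log tau, log sigma)` targeting their
conditional with the contrasts integrated out — valid because the
contrasts are redrawn from their full conditional immediately afterwards.
There are no tuned step sizes affecting correctness; the contract is the
stationary distribution, which the tests check against a closed-form
conjugate oracle in the two-device complete-pairing case.

A variance floor of 1e-8 keeps degenerate inputs (for example, all
respondents giving identical scores) finite instead of letting the
residual variance underflow.

Defaults: 2 chains of 100 000 iterations including a 20 000-iteration
burn-in (we read the study's "100 000 iterations" as the total per run),
thinning 1, seed mandatory. Chains beyond the first start from
overdispersed initial values. Convergence is summarised by split-chain
Gelman–Rubin statistics and effective sample sizes computed for every
parameter; `fit_gus_model()` attaches a convergence flag (all split-Rhat
below 1.05) and warns — never silently — when it fails.

## DIC and model selection

`compute_dic()` reports `Dbar` (posterior mean deviance), `pD = Dbar -
Dhat` with `Dhat` the deviance at the posterior means of the parameters,
and `DIC = Dbar + pD`. For the RE model the deviance is **marginal** over
the latent contrasts (closed form under independence: baseline arms have
variance `tau^2`, contrast arms `tau^2 + sigma^2`). A conditional,
contrast-level deviance would let the random effects chase residual noise
and systematically favour RE regardless of the data; the marginal
deviance puts FE and RE on the same data distribution so their DICs are
comparable. `select_model()` keeps the simpler FE model unless RE
improves the DIC by at least 3 points.

Even so, the FE/RE comparison has limited resolution at this design size:
the information separating `sigma^2` from `tau^2` comes only from the
~55 multi-arm respondents' contrast covariances, whose moment estimator
has a standard error of roughly 7 GUS-points-squared. A homogeneous
cohort can therefore exhibit chance apparent heterogeneity large enough
that preferring RE is the *correct* reading of that dataset; conversely
moderate true heterogeneity may go undetected, which is worth remembering
when interpreting a real study's FE selection.

## Presentation scale and ranks

Device effects are relative to the reference. For presentation on the
absolute GUS scale each iteration is anchored at that iteration's mean
respondent intercept `A = mean(mu_i)` and `G_k = A + d_k` is summarised
by its posterior mean and central 95% credible interval (the reference
device's summary is exactly the summary of `A`; with no contrast signal
every device's summary collapses to the cohort mean). The published
figure's anchoring construction is not stated, so this is the package's
own choice, made once.

`rank_probabilities()` ranks devices by `G_k` within each iteration
(rank 1 = highest usability; exact ties break by canonical device order,
making the matrix invariant to input record order) and reports the
devices-by-ranks probability matrix, which is doubly stochastic up to
Monte Carlo error.

# Cohort-level statistics

`prop_diff_ci()` implements the difference of two independent proportions
with a 95% Wald interval including a continuity correction,

```
delta +/- [ 1.96 * sqrt(p1 q1 / n1 + p2 q2 / n2) + (1/n1 + 1/n2) / 2 ] * 100
```

clipped to [-100, 100]. This method was chosen because it reproduces the
published interval for the MDI-experience comparison (19.6–58.2
percentage points from 52.7% of 74 vs 13.8% of 29) where the plain and
pooled-variance Wald intervals do not — an inference about the original
analysis' method, which is not named. The attached p-value is the Yates
chi-squared test on the implied 2x2 counts. `chi_square_test()` is the
Pearson test without continuity correction, and `anova_from_summary()`
reconstructs one-way ANOVA from group means, sds and sizes, for
verifying baseline tables when only summaries are printed.

# The synthetic cohort generator

No respondent-level data are deposited for the study this package
emulates, so `generate_cohort()` provides cohorts with known ground
truth:

```
y_ik = clamp(round(mu_i + e_k + eta_ik + eps_ik), 0, 50)
```

with `mu_i ~ N(anchor, respondent_sd^2)`, `eps ~ N(0, residual_sd^2)`,
and `eta ~ N(0, heterogeneity_sd^2)` on non-reference arms only (see the
identifiability discussion: effect heterogeneity is a property of the
relative effects). Defaults, chosen once as realistic for this
instrument: `anchor = 25` (mid-scale, keeping truncation negligible for
effects within ±15 points), `respondent_sd = 5`, `residual_sd = 5`
(matching the residual scale used in the recovery analyses),
`heterogeneity_sd = 0` (fixed-effect truth, as selected for the real
cohorts), true effects `(0, 2, 10, -4, 4, 6, 8)` in canonical device
order, integer rounding (sub-scores are integer point awards), truncation
at the scale bounds with the truncation rate recorded and a warning when
it exceeds 5%.

What the generator emulates: the exact group structure and sample sizes,
respondent-level heterogeneity, additive device effects, integer scores
on 0–50. What it does not emulate: item-level response psychology
(box sub-scores are only reconstructed post hoc by
`inverse_questionnaire()`), covariate structure (age, smoking, disease
severity are descriptive only), learning or order effects within a
session, and any non-normality of real GUS totals. Passing tests
therefore demonstrate that the machinery recovers truth under the model's
own assumptions at this design size — not that the published cohort's
numerical results are reproduced, which is impossible without the raw
data.

# Problem sizes used by the test suite

Module tests run the sampler at 2 chains of 2 000–8 000 iterations on
cohorts of 10–74 respondents, sizes at which the conjugate oracle and
determinism checks are sharp. The acceptance-level distributional checks
use 2 chains of 20 000 iterations (a deliberate scale-down of the
100 000-iteration default, which leaves Monte Carlo error well below the
tolerances tested), 20 replicate cohorts of the full design for coverage
and model-selection frequencies, and at least 10^4 draws for the
doubly-stochastic rank-matrix check. The large-cohort law-of-large-numbers
check scales the design a hundredfold.

# Known limitations

* `tau` and `sigma` are only weakly identified even in the independent-
  contrast parameterisation; their posteriors on a 103-respondent design
  are broad, and FE/RE selection frequencies reflect that.
* The default scoring scheme is a structural placeholder, not the
  validated instrument's weights; analyses of real questionnaires must
  supply their own scheme JSON.
* The pipeline analyses strata strictly separately (as the emulated study
  did); there is no pooled or meta-regression mode.
* Consistency/inconsistency (node-splitting) assessment and SUCRA-style
  rank summaries beyond the rank-probability matrix are out of scope.
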