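---
title: "Modelling AAA growth from longitudinal diameter and volume measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling AAA growth from longitudinal diameter and volume measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaagrowth)
```

## The problem

Small abdominal aortic aneurysms (AAA) are monitored rather than operated:
serial CT measurements of the maximum aortic diameter (mm) — and, where
available, of the aneurysm volume (ml) — are collected roughly every six
months until the 55 mm surgery threshold is approached. Two questions drive
the analyses this package implements:

1. What is the distribution of relative size growth across a monitored
   population, and how well can an individual's future size be predicted
   from a baseline measurement?
2. Do volume and maximum diameter grow at the same pace within a patient,
   once the geometric units are reconciled? Volume scales as a length cubed,
   so volume is compared on the cube-root scale $V^{1/3}$.

## The stochastic growth model

Each subject $i$ has a latent average exponential growth rate
$\lambda_i > 0$ per year, so the expected relative growth over $t$ years is
$e^{\lambda_i t}$. Three stochastic layers complete the model:

* **Between subjects**: $\log \lambda_i \sim N(\mu, \tau^2)$. The lognormal
  captures the familiar right skew — most aneurysms grow slowly, a few grow
  fast.
* **Within subject**: growth fluctuates over time. Conditional on
  $\lambda_i$, log-size follows Brownian motion with drift
  $\lambda_i - \sigma_w^2/2$ and volatility $\sigma_w$ (per $\sqrt{\text{yr}}$),
  i.e. geometric Brownian motion. The drift correction makes
  $E[X(t)/X(0) \mid \lambda_i] = e^{\lambda_i t}$ hold *exactly*, which is
  the defining property we impose; an alternative convention placing
  $\lambda$ itself on the log-scale drift would make $e^{\lambda t}$ the
  median rather than the mean of the conditional growth factor. Both
  conventions differ only through $\sigma_w^2/2$, which is small here, but
  the package treats the mean convention as normative.
* **Measurement**: each reading carries multiplicative lognormal error with
  log-scale SD $\sigma_m$. Reader agreement for these measurements is
  excellent (intraclass correlations near 1), so $\sigma_m$ is expected to
  be tiny; it is estimated by default and can be fixed (e.g. at 0) with
  `fix_sigma_m`.

Increments of observed log-size from the first visit are then multivariate
normal given $\lambda_i$, with covariance
$\sigma_w^2 \min(t_j, t_k) + \sigma_m^2 (1 + 1[j = k])$ (the shared baseline
reading induces the constant term). The marginal likelihood integrates
$\lambda_i$ out by Gauss–Hermite quadrature (order 64 by default; the order
is configurable but must be at least 8). Subjects with a single usable visit
carry no information about growth and contribute zero; they are flagged and
excluded from rate estimation.

### Fitting

`fit_growth_model()` maximises the marginal likelihood over
$(\mu, \tau, \sigma_w, \sigma_m)$, with the non-negative parameters
log-transformed. A Nelder–Mead simplex search runs first — the surface has a
degenerate ridge (tiny $\lambda$ with inflated $\sigma_w$) that a
quasi-Newton method can fall onto from poor starts — followed by an
L-BFGS-B polish on the box $[\exp(-9.2), \cdot]$ for the SDs; convergence is
assessed at a relative tolerance of about $10^{-8}$ on the log-likelihood.
Starting values are data-driven: the population rate scale from per-subject
overall log-slopes, the diffusion scale from detrended consecutive
increments. Standard errors come from the observed information at the
optimum, delta-methoded back to the natural scale, and are reported as `NA`
when a parameter sits on its boundary (flat data drive $\tau$ and
$\sigma_w$ to the floor, with a warning).

### Growth distribution and prediction

The population growth factor over $t$ years is
$G = \exp((\lambda - \sigma_w^2/2) t + \sigma_w \sqrt{t} Z)$. Its CDF is a
Gauss–Hermite average of normal CDFs; quantiles are found by bracketed root
finding (tolerance far below $10^{-8}$ on $G$), and the mean
$E[G] = E[e^{\lambda t}]$ by quadrature (no closed form under a lognormal
$\lambda$). Two deliberate conventions:

* **Population quantiles** (`growth_distribution_quantile()`, the reference
  curves and the growth table) *exclude* measurement error: they describe
  latent true sizes.
* **Predictive quantiles** (`predictive_quantile()`, used in validation)
  *include* it by default, because the prediction target is a future
  reading; the baseline is conditioned on as observed.

Absolute growth at a starting value $v$ is exactly $v/100$ times the
relative growth in percent — the growth table preserves this identity to
machine precision.

### Individual rates

Given the fitted population parameters, `individual_rates()` estimates each
subject's $\lambda_i$ by bounded 1-D optimisation on $\log\lambda$. The
default is the posterior mode (likelihood times the lognormal population
density): pure conditional maximum likelihood is also provided, but for a
shrinking series it degenerates toward the $\lambda \to 0$ boundary of the
lognormal support, while the MAP estimate stays interior and shrinks noisy
series toward the population — the behaviour one wants when rates are
subsequently compared across scales. Rates are reported as percent per
year, $100(e^{\lambda} - 1)$.

## The volume–diameter relation

Across a population, volume is approximately proportional to the cube of
the maximum diameter. `fit_size_relation()` fits
$V_{ij}^{1/3} = (a + \alpha_i) d_{ij} + \epsilon_{ij}$ with no intercept,
random slope $\alpha_i \sim N(0, \sigma_a^2)$ and residual
$\epsilon_{ij} \sim N(0, \sigma_e^2)$, by direct marginal likelihood: the
rank-one covariance $\sigma_a^2 d d^\top + \sigma_e^2 I$ admits closed-form
GLS for $a$ (Sherman–Morrison), leaving a 2-D optimisation over the
variance components. This keeps the estimator self-contained and
convention-free; an independent mixed-model implementation is used as a
cross-check in the test suite, not as the estimator.

The implied volume distribution at diameter $d$ is
$V_p = ((\hat a + z_p \hat\sigma_a) d)^3$ — only between-subject slope
variability enters, since the question is how volumes vary *across patients*
at a given diameter; `include_residual = TRUE` adds visit-level scatter.
Normal quantiles $z_p$ are used at full floating precision, not rounded.
As a geometric illustration, for an ellipsoidal aneurysm with circular
cross sections `ellipsoid_ratio()` converts a (diameter, volume) pair into
the diameter-to-height ratio $d/h = d^3/V \cdot \pi/6$ (volume converted
ml→mm³ internally); it equals 1 for a sphere.

Association on the common scale is quantified two ways:
`baseline_pearson()` across first visits, and
`repeated_measures_correlation()` — the Bland–Altman coefficient, the signed
square root of the variation in one variable explained by the other after
adjusting for subject as a fixed effect.

## Comparing growth rates across scales

`compare_rates()` fits-and-estimates nothing itself: it takes the two
fitted parameter sets (diameter and cube-root volume), estimates per-subject
rates on each scale, and forms the ratio of the *percent-per-year* rates —
the reported convention; a flag switches to raw-$\lambda$ ratios, which
differ only at second order. Ratios are categorised into five classes with
an equivalence band of $[0.8, 1.25]$, closed at both ends (the band is
log-symmetric: $\log 1.25 = -\log 0.8$); $[0.5, 0.8)$ and $(1.25, 2]$ are
moderate, beyond that considerable. Boundary inclusion is a documented
tie-break and affects no generic-position data. The volume percent rate is
derived from the cube-root rate by the cube law.

## Validation

`loocv_calibration()` refits the model once per held-out subject (warm
started at the full-data optimum) and predicts the subject's final reading
from their baseline value and elapsed time. Coverage at nominal level $q$
is compared against $q$ with the perfect-model binomial SE
$100\sqrt{q(1-q)/n}$; ties (`observed == quantile`) count as covered, and
$n$ is the number of subjects actually entering the calibration
(single-visit subjects logically cannot contribute; the CLI reports both
$n$ conventions). `bootstrap_se()` provides nonparametric
resample-subjects SEs for any statistic (default $B = 200$, seeded); the
bootstrap was preferred over the delta method for quantile SEs because it
needs no analytic derivatives of root-finding output.

## The synthetic-cohort generator

No patient-level data ship with the package, so `simulate_cohort()`
generates cohorts with the structure the analyses assume: 84 subjects by
default, visits every 0.5 years with SD 0.06 jitter, 1–9 visits per subject
from a truncated geometric with continuation probability 0.87 (median 4),
baseline diameter lognormal with median 47 mm and log-SD 0.17 truncated to
[30, 68] mm, diameter rates lognormal with median 3.8 %/yr
(`mu_log_rate = log(0.038)`) and `tau_log_rate = 0.6`, diffusion
`sigma_w = 0.05`, measurement error `sigma_m = 0.01`, cube-law slope
$N(0.0926, 0.0108^2)$ (these reproduce the reference volume quantiles at
55 mm and give a baseline volume median near 81 ml), and a lognormal rate
ratio with log-SD 0.45 linking the cube-root-volume rate to the diameter
rate (chosen so that all five ratio classes are populated, with roughly
log-symmetric scatter about the identity). `truth_class_probabilities()`
returns the implied class probabilities by high-n Monte Carlo over the
generator's joint distribution — the percent-rate ratio depends jointly on
the rate and the ratio, so a pure normal-CDF calculation on $\log R$ would
only be approximate; the method is recorded in the result.

The generator is a test harness, not a cohort-emulation claim: it does not
model dropout, thrombus, covariate-dependent growth, correlated
diameter/volume diffusion, or reader-specific error, and the true joint
distribution of diameter- and volume-rate deviations in patients is
unknown. Passing recovery and calibration tests on simulated data therefore
demonstrates internal consistency of the estimators under the assumed
model, not clinical validity.

## Numerical choices and problem sizes

* Gauss–Hermite order 64 for fitting and quantiles (32 in the
  cross-validation loops, where hundreds of refits occur and the integrand
  is smooth); the order is validated to be ≥ 8.
* Positive parameters floored at $10^{-4}$ on the natural scale; hitting
  the floor raises a boundary warning and suppresses that SE.
* Quantile root finding on $\log G$ with `uniroot` tolerance $10^{-12}$.
* Degenerate cases ($\tau = 0$ or zero total diffusion) use closed forms
  instead of quadrature/root finding.
* Report tables round half-away-from-zero to one decimal, with
  full-precision companions always emitted.
* The test suite exercises parameter recovery at 200 subjects × 6 visits,
  leave-one-out calibration at 300 subjects, and class-proportion
  consistency at 2000 subjects — sizes at which recovery tolerances and
  3-SE calibration bands are comfortably informative while the whole suite
  runs in minutes on a laptop.

## Known limitations

* Growth rates are time-constant per subject; no covariate effects on
  $\lambda$ and no rupture-risk modelling.
* The size-relation model is linear in $d$ on the cube-root scale; no
  spline or thrombus-aware extensions.
* Two modelling conventions are genuinely open — where the drift correction
  sits on the log scale, and whether measurement error belongs in the
  likelihood. The conventions above (mean-preserving drift; estimated
  $\sigma_m$) are this package's normative contract, and both switches
  (`fix_sigma_m`, `include_measurement_error`) are exposed.
* Reader averaging is assumed upstream: the loader accepts already-averaged
  measurements and does not model reader variance.
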