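# aaagrowth

Stochastic growth modelling of abdominal aortic aneurysm (AAA) size from
longitudinal CT measurements.

Small AAAs are kept under surveillance: maximum aortic diameter (mm) and,
increasingly, aneurysm volume (ml) are measured roughly every six months
until the 55 mm surgery threshold is approached. This package is for
biostatisticians and vascular-research groups who want to characterise the
growth distribution of such a cohort, predict an individual's future size
from a baseline measurement, relate volume to diameter through the
geometric cube law, and ask whether volume and diameter grow at the same
pace within a patient.

## The model

Each subject $i$ carries a latent average growth rate $\lambda_i$ (per
year), so expected relative growth over $t$ years is $e^{\lambda_i t}$.
Across subjects $\log\lambda_i \sim N(\mu, \tau^2)$ (lognormal rates:
most aneurysms grow slowly, a few fast). Within a subject, log-size follows
geometric Brownian motion with volatility $\sigma_w$ and drift
$\lambda_i - \sigma_w^2/2$ (so the conditional expectation is exactly
$e^{\lambda_i t}$), and each reading adds multiplicative lognormal
measurement error with log-SD $\sigma_m$. The marginal likelihood
integrates $\lambda_i$ out by Gauss–Hermite quadrature;
`fit_growth_model()` maximises it over $(\mu, \tau, \sigma_w, \sigma_m)$.

The volume–diameter relation is modelled on the cube-root scale with a
random slope and no intercept, $V_{ij}^{1/3} = (a + \alpha_i) d_{ij} +
\epsilon_{ij}$, giving the population volume distribution at a diameter
$d$ as $V_p = ((\hat a + z_p \hat\sigma_a) d)^3$. Growth rates of
cube-root volume and diameter are compared per subject through the ratio
of their percent-per-year rates, classified with an equivalence band of
[0.8, 1.25].

See `vignette("aaa-growth-model")` for the full account of the model,
conventions, numerical choices and limitations.

## Worked example

```r
library(aaagrowth)

sim <- simulate_cohort(simulation_config(seed = 1))   # 84 synthetic subjects
fit <- fit_growth_model(sim$cohort, scale = "volume")
summary(fit)
#> Stochastic growth model fit (volume scale)
#>   68 subjects (16 single-visit excluded); log-likelihood 160.854
#> Growth-model parameters (volume scale):
#>   mu_log_rate   -2.0136   (median rate 14.28 %/yr)
#>   tau_log_rate   0.2095
#>   sigma_w        0.1513   per sqrt(yr)
#>   sigma_m        0.0478
#> ...
#> Population median growth rate: 14.28 %/yr

round(growth_quantile_table(fit$params, levels = c(.05, .25, .5, .75, .95))[-1], 1)
#>   initial_value mean_increase  q5 q25  q50  q75 q95
#> 1           100          14.7 -12 2.1 13.3 25.7  46
#> 2            50           7.3  -6 1.1  6.7 12.9  23
#> 3           100          14.7 -12 2.1 13.3 25.7  46
#> 4           150          22.0 -18 3.2 20.0 38.6  69
```

The first row is the 1-year relative growth distribution in percent (here:
median 13.3 %/yr, mean 14.7 %/yr — the simulated cohort's volume growth);
the absolute rows (ml) at starting volumes 50/100/150 ml are exact
proportional rescalings of it. The fitted `sigma_w` says volume
trajectories wobble around their exponential trend with SD ≈ 15 % per
√year; `sigma_m` is the per-reading error.

```r
sr <- fit_size_relation(sim$cohort)
sr
#> Random-slope cube-law model: V^(1/3) = (a + alpha_i) * d + eps
#>   a_hat   0.09398 ml^(1/3)/mm
#>   sigma_a 0.01141
#>   sigma_e 0.28378
#>   84 subjects, 331 paired visits; log-likelihood -162.485
#>   median volume at 55 mm: 138.1 ml

round(ellipsoid_ratio(55, volume_quantile_at_diameter(sr, 55, 0.5)), 2)
#> [1] 0.63       # median synthetic aneurysm at 55 mm: wider than tall
```

The median subject-specific shape factor `a_hat^3` cubes the slope into
`V = s d^3`; `ellipsoid_ratio()` translates any (diameter, volume) pair
into the diameter-to-height ratio of an idealised ellipsoidal aneurysm
(1 = sphere). Predictive quantiles and their leave-one-out calibration come
from `predict(fit, ...)` and `loocv_calibration()`; per-subject rates and
the diameter-vs-volume comparison from `individual_rates()` and
`compare_rates()`.

A thin command-line wrapper over the same functions ships in
`inst/cli/aaagrowth.R` (`simulate`, `fit`, `quantiles`, `size-relation`,
`loocv`, `compare`, `ellipsoid`, ...).

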