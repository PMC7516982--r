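# oepiv

Parametric survival analysis with the **odds exponential-Pareto IV
(OEPIV)** distribution and its log-location-scale regression model for
right-censored data.

The OEPIV family arises from the T-X construction: the Pareto IV odds
ratio F/(1−F) is passed through a unit-rate exponential generator,
giving the survival function

    S(x) = exp{ −λ [ (1 + (x/θ)^(1/a))^α − 1 ] },   x > 0,

with shape parameters λ, α > 0, scale θ > 0 and inequality parameter
a > 0. The family accommodates decreasing, increasing and upside-down
hazards; α = 1 recovers a Weibull law (shape 1/a, scale θλ^−a) and
λ = a = θ = α = 1 the unit exponential. On the log scale, Y = log X
follows the LOEPIV location-scale law (σ = a, μ = log θ), which serves
as the error distribution of the accelerated-failure-time-style
regression

    y_i = βᵀx_i + σ z_i,

fitted to right-censored data by maximum likelihood or the jackknife.

The package is aimed at biostatisticians and reliability analysts who
want this family as a drop-in parametric alternative to Weibull-type
AFT models, together with the model-checking toolkit that goes with it:
martingale and deviance residuals, simulated normal-probability-plot
envelopes, generalized Cook and likelihood-distance case-deletion
diagnostics, and a Monte Carlo harness for estimator bias/MSE studies.

## What's inside

* `doepiv`/`poepiv`/`qoepiv`/`roepiv`/`hoepiv` — density, distribution,
  quantile, random variates and hazard, all evaluated in log space so
  extreme parameters and tails stay accurate; moments, mode, order
  statistics, Renyi entropy (`oepiv_moment`, `oepiv_moments`,
  `oepiv_mode`, `doepiv_order`, `oepiv_renyi`).
* `dloepiv` and friends, plus the standardized error law
  (`dloepiv_err`, …) of the regression model.
* `fit_oepiv()` — maximum likelihood with analytic score, Newton
  polishing, delta-method covariance; broom-style `tidy()`/`glance()`
  and ggplot2 `autoplot()`.
* `loepiv_reg()` — censored log-location-scale regression with a
  `survival::Surv()` formula interface; `predict()`, `residuals()`,
  `augment()`, `loepiv_jackknife()`, `loepiv_influence()`,
  `simulated_envelope()`, `km_curve()`.
* `oepiv_sim_study()`, `residual_study()`, `calibrate_censoring_rho()`,
  `simulate_loepiv_reg()`, `generate_fixture()` — the simulation
  engine and synthetic-data generators.
* A thin command-line interface (`inst/cli/oepiv.R`) with `fit`,
  `regress`, `diagnose`, `simulate` and `generate` subcommands.

## Worked example

Draw a sample from the distribution, fit it back, then fit and check
the censored regression:

```r
library(oepiv)

x <- roepiv(500, 0.3, 0.4, 0.5, 0.2, seed = 42)
fit <- fit_oepiv(x)
fit
#> OEPIV maximum-likelihood fit (n = 500 )
#>            lambda       a   theta   alpha
#> estimate  0.33276 0.47995 0.53046 0.23565
#> std.error 0.10987 0.07661 0.13102 0.03782
#> log-likelihood: -1725.87   AIC: 3459.739   converged: TRUE
```

All four generating parameters (0.3, 0.4, 0.5, 0.2) are recovered
within about one standard error. The regression model, on data
simulated from the censored design with a uniform covariate and 10%
censoring:

```r
d <- simulate_loepiv_reg(300, 0.3, 0.36, 0.6, -0.6, 1,
                         censor_level = 0.1, seed = 11)
reg <- loepiv_reg(survival::Surv(time, status) ~ x1, data = d)
tidy(reg)
#> # A tibble: 5 × 5
#>   term        estimate std.error statistic     p.value
#>   <chr>          <dbl>     <dbl>     <dbl>       <dbl>
#> 1 (Intercept)   -0.839    0.328      -2.56 0.0106
#> 2 x1             1.42     0.274       5.17 0.000000240
#> 3 sigma          0.388    0.0932      4.17 0.0000310
#> 4 lambda         0.348    0.177       1.97 0.0490
#> 5 alpha          0.213    0.0481      4.43 0.00000962

tidy(loepiv_jackknife(reg))
#> # A tibble: 5 × 5
#>   term        estimate std.error conf.low conf.high
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl>
#> 1 (Intercept)   -0.830    0.326    -1.47     -0.191
#> 2 x1             1.41     0.289     0.844     1.98
#> 3 sigma          0.405    0.0906    0.228     0.583
#> 4 lambda         0.301    0.181     0         0.656
#> 5 alpha          0.225    0.0515    0.124     0.326
```

The ML and jackknife estimates agree to well within one standard error
on every component (the jackknife interval for λ is floored at zero, as
befits a positive parameter). Covariate effects translate into survival
curves:

```r
predict(reg, tibble::tibble(x1 = c(0.2, 0.8)), log_time = 0)
#> # A tibble: 2 × 3
#>    .row log_time survival
#>   <int>    <dbl>    <dbl>
#> 1     1        0    0.864
#> 2     2        0    0.971
```

i.e. at log-time 0 the fitted survival probability is 86% for a subject
with x1 = 0.2 and 97% for x1 = 0.8 — larger covariate values prolong
survival, as the positive slope dictates. Model checking uses the
residual toolkit, e.g. `autoplot(simulated_envelope(reg, seed = 1))`
for the deviance-residual normal probability plot with a simulated
envelope and `autoplot(loepiv_influence(reg))` for case-deletion index
plots.

See the methods vignette (`vignettes/oepiv-methods.Rmd`) for the model,
the numerical design, the boundary-drift convergence policy and the
known limitations.

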