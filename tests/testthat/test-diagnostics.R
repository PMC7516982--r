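fit_for_diag <- function(n = 60, censor_level = 0.15, seed = 122) {
  d <- reg_fixture(n = n, censor_level = censor_level, seed = seed)
  withr::with_seed(seed + 1,
                   loepiv_reg(survival::Surv(time, status) ~ x1, data = d))
}

test_that("martingale residuals equal status plus log survival", {
  fit <- fit_for_diag()
  rM <- residuals(fit, type = "martingale")
  mu <- drop(fit$X %*% fit$coefficients)
  oracle <- fit$status + ploepiv(fit$y, fit$lambda, fit$alpha, fit$sigma,
                                 mu, lower.tail = FALSE, log.p = TRUE)
  expect_equal(rM, oracle, tolerance = 1e-10)
  expect_true(all(rM <= 1))
  # censored residuals are non-positive
  expect_true(all(rM[fit$status == 0] <= 0))
})

test_that("deviance transform is sign-preserving, monotone, and correct", {
  fit <- fit_for_diag()
  rM <- residuals(fit, type = "martingale")
  rD <- residuals(fit, type = "deviance")
  expect_equal(sign(rD), sign(rM))
  # branch formulas recomputed independently
  d <- fit$status
  oracle <- sign(rM) * sqrt(-2 * (rM + d * log(d - rM)))
  expect_equal(rD, oracle, tolerance = 1e-12)
  # censored branch: rM = -0.5 maps to -1
  expect_equal(sign(-0.5) * sqrt(-2 * -0.5), -1)
  # monotone in rM within each censoring branch
  for (s in c(0, 1)) {
    idx <- order(rM[d == s])
    expect_true(all(diff(rD[d == s][idx]) >= 0))
  }
})

test_that("martingale residuals center near zero on well-specified data", {
  d <- reg_fixture(n = 2000, censor_level = 0.1, seed = 120)
  fit <- withr::with_seed(11, loepiv_reg(survival::Surv(time, status) ~ x1,
                                         data = d))
  expect_lt(abs(mean(residuals(fit, "martingale"))), 0.05)
})

test_that("influence measures vanish in the no-influence case", {
  fit <- fit_for_diag()
  theta <- coef(fit)
  loo_null <- matrix(rep(theta, each = fit$n), fit$n,
                     dimnames = list(NULL, names(theta)))
  infl <- suppressWarnings(loepiv_influence(fit, loo = loo_null))
  expect_equal(infl$gd, rep(0, fit$n), tolerance = 1e-10)
  expect_equal(infl$ld, rep(0, fit$n), tolerance = 1e-8)
  jk <- loepiv_jackknife(fit, loo = loo_null)
  expect_equal(unname(jk$estimate), unname(theta), tolerance = 1e-12)
  expect_equal(unname(jk$std_errors), rep(0, 5), tolerance = 1e-12)
})

test_that("a planted gross outlier attains the maximal influence", {
  d <- reg_fixture(n = 100, censor_level = 0, seed = 141)
  # plant the outlier on the median observation so it is unambiguous
  idx <- which.min(abs(d$time - stats::median(d$time)))
  d$time[idx] <- d$time[idx] * 100
  fit <- withr::with_seed(142, loepiv_reg(survival::Surv(time, status) ~ x1,
                                          data = d))
  loo <- withr::with_seed(13, loepiv_loo(fit))
  infl <- suppressWarnings(loepiv_influence(fit, loo = loo))
  expect_equal(which.max(infl$gd), idx)
  expect_equal(which.max(infl$ld), idx)
  expect_true(infl$flagged[idx])
  expect_true(all(infl$ld > -1e-6, na.rm = TRUE))
  expect_gt(stats::cor(infl$gd, infl$ld, method = "spearman",
                       use = "complete.obs"), 0)
})

test_that("Cook distances are invariant to covariate column reordering", {
  d <- reg_fixture(n = 100, censor_level = 0, seed = 152)
  d$x2 <- withr::with_seed(15, stats::runif(100))
  f12 <- withr::with_seed(16,
    loepiv_reg(survival::Surv(time, status) ~ x1 + x2, data = d))
  f21 <- withr::with_seed(16,
    loepiv_reg(survival::Surv(time, status) ~ x2 + x1, data = d))
  loo12 <- withr::with_seed(17, loepiv_loo(f12))
  loo21 <- withr::with_seed(17, loepiv_loo(f21))
  g12 <- suppressWarnings(loepiv_influence(f12, loo = loo12))$gd
  g21 <- suppressWarnings(loepiv_influence(f21, loo = loo21))$gd
  expect_equal(g12, g21, tolerance = 1e-4)
})

test_that("Kaplan-Meier curve matches hand-computed product limits", {
  km <- km_curve(tibble::tibble(time = c(1, 2, 3), status = 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  km0 <- km_curve(tibble::tibble(time = c(1, 2, 3), status = 0))
  expect_true(all(km0$survival == 1))
  # mixed toy set: events at 1, 3, 5; censorings at 2, 4, 6
  km2 <- km_curve(tibble::tibble(time = 1:6,
                                 status = c(1, 0, 1, 0, 1, 0)))
  surv_at <- function(t) km2$survival[max(which(km2$time <= t))]
  expect_equal(surv_at(1), 5 / 6, tolerance = 1e-12)
  expect_equal(surv_at(3), 5 / 6 * 3 / 4, tolerance = 1e-12)
  expect_equal(surv_at(5), 5 / 6 * 3 / 4 * 1 / 2, tolerance = 1e-12)
  expect_error(km_curve(tibble::tibble(time = c(-1, 2), status = 1)),
               "positive")
})

test_that("simulated envelope is reproducible and covers self-simulated data", {
  fit <- fit_for_diag(n = 150, censor_level = 0.1, seed = 182)
  env1 <- simulated_envelope(fit, n_sim = 19, seed = 99)
  env2 <- simulated_envelope(fit, n_sim = 19, seed = 99)
  expect_equal(env1, env2)
  expect_error(simulated_envelope(fit, n_sim = 10), "19")
  # data simulated from the fitted model: most points inside the band
  inside <- mean(env1$observed >= env1$lower & env1$observed <= env1$upper)
  expect_gte(inside, 0.9)
  expect_true(all(env1$lower <= env1$median & env1$median <= env1$upper))
})

test_that("augment returns the residual columns alongside the fit", {
  fit <- fit_for_diag()
  au <- augment(fit)
  expect_named(au, c("y", "status", ".fitted", ".z", ".martingale",
                     ".deviance"))
  expect_equal(au$.martingale, residuals(fit, "martingale"))
  expect_equal(nrow(au), fit$n)
})

test_that("diagnostic autoplot methods return ggplot objects", {
  fit <- fit_for_diag(n = 80, censor_level = 0.1, seed = 170)
  loo <- withr::with_seed(18, loepiv_loo(fit))
  infl <- suppressWarnings(loepiv_influence(fit, loo = loo))
  expect_s3_class(autoplot(infl), "ggplot")
  fit2 <- fit_for_diag(n = 150, censor_level = 0.1, seed = 182)
  env <- simulated_envelope(fit2, n_sim = 19, seed = 1)
  expect_s3_class(autoplot(env), "ggplot")
  funi <- withr::with_seed(20, fit_oepiv(roepiv(100, 1, 1, 1, 1,
                                                seed = 2)))
  expect_s3_class(autoplot(funi), "ggplot")
  expect_s3_class(autoplot(funi, type = "survival"), "ggplot")
})
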