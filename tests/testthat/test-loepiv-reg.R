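test_that("censored log-likelihood matches per-record reductions", {
  # single event at the unit-parameter median
  y0 <- log(log(2))
  expect_equal(loepiv_censored_loglik(y0, 1, matrix(1), 0, 1, 1, 1),
               dloepiv(y0, 1, 1, 1, 0, log = TRUE), tolerance = 1e-12)
  # single censored record at z = 0: contribution lambda - lambda * 2^alpha
  expect_equal(loepiv_censored_loglik(0, 0, matrix(1), 0, 1, 1, 1),
               1 - 2, tolerance = 1e-12)
  expect_equal(loepiv_censored_loglik(0, 0, matrix(1), 0, 1, 1, 1.7),
               1 - 2^1.7, tolerance = 1e-12)
  # 50 mixed records against the sum-of-logs oracle
  d <- reg_fixture(n = 50, censor_level = 0.3, seed = 33)
  y <- log(d$time)
  X <- cbind(1, d$x1)
  th <- list(beta = c(-0.5, 0.9), sigma = 0.7, lambda = 0.4, alpha = 0.3)
  mu <- drop(X %*% th$beta)
  oracle <- sum(ifelse(d$status == 1,
                       dloepiv(y, th$lambda, th$alpha, th$sigma, mu,
                               log = TRUE),
                       ploepiv(y, th$lambda, th$alpha, th$sigma, mu,
                               lower.tail = FALSE, log.p = TRUE)))
  expect_equal(loepiv_censored_loglik(y, d$status, X, th$beta, th$sigma,
                                      th$lambda, th$alpha),
               oracle, tolerance = 1e-10)
})

test_that("structured errors name the offending input", {
  expect_error(loepiv_censored_loglik(c(1, 2), c(1, 2), cbind(c(1, 1)),
                                      0, 1, 1, 1), "row")
  expect_error(loepiv_censored_loglik(1:3, c(1, 1), cbind(rep(1, 2)),
                                      0, 1, 1, 1), "matching")
})

test_that("ML fit recovers the censored regression design parameters", {
  d <- reg_fixture(n = 1000, censor_level = 0.1, seed = 55)
  fit <- withr::with_seed(1, loepiv_reg(survival::Surv(time, status) ~ x1,
                                        data = d))
  expect_true(fit$converged)
  expect_false(fit$boundary)
  truth <- c(-0.6, 1, 0.6, 0.3, 0.36)
  est <- coef(fit)
  expect_true(all(abs(est - truth) / fit$std_errors < 3))
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
  expect_equal(unname(fit$std_errors), unname(sqrt(diag(fit$vcov))),
               tolerance = 1e-12)
})

test_that("uncensored intercept-only fit matches the OEPIV fit of exp(y)", {
  x <- roepiv(400, set_1[1], set_1[2], set_1[3], set_1[4], seed = 66)
  d <- tibble::tibble(time = x, status = 1)
  freg <- withr::with_seed(2,
    loepiv_reg(survival::Surv(time, status) ~ 1, data = d))
  funi <- withr::with_seed(3, fit_oepiv(x))
  # mapping: sigma = a, mu = log theta
  expect_equal(freg$loglik - sum(log(x)),   # Jacobian of y = log x
               funi$loglik, tolerance = 1e-6)
  expect_equal(freg$sigma, unname(funi$estimates["a"]), tolerance = 1e-4)
  expect_equal(unname(freg$coefficients[1]),
               log(unname(funi$estimates["theta"])), tolerance = 1e-4)
  expect_equal(freg$lambda, unname(funi$estimates["lambda"]),
               tolerance = 1e-4)
  expect_equal(freg$alpha, unname(funi$estimates["alpha"]),
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected, not silently fitted", {
  d <- reg_fixture(n = 30, seed = 5)
  d$status <- 0
  expect_error(loepiv_reg(survival::Surv(time, status) ~ x1, data = d),
               "events")
  d2 <- reg_fixture(n = 30, seed = 6)
  d2$x2 <- d2$x1 * 2
  expect_error(loepiv_reg(survival::Surv(time, status) ~ x1 + x2,
                          data = d2), "rank")
  d3 <- reg_fixture(n = 30, seed = 7)
  d3$time[4] <- -1
  expect_error(loepiv_reg(survival::Surv(time, status) ~ x1, data = d3),
               "positive")
})

test_that("time rescaling shifts the intercept and nothing else", {
  d <- reg_fixture(n = 200, censor_level = 0.1, seed = 71)
  f1 <- withr::with_seed(4, loepiv_reg(survival::Surv(time, status) ~ x1,
                                       data = d))
  d2 <- dplyr::mutate(d, time = time * exp(2))
  f2 <- withr::with_seed(4, loepiv_reg(survival::Surv(time, status) ~ x1,
                                       data = d2))
  expect_equal(unname(f2$coefficients[1]), unname(f1$coefficients[1]) + 2,
               tolerance = 1e-4)
  expect_equal(unname(f2$coefficients[2]), unname(f1$coefficients[2]),
               tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-4)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-4)
})

test_that("predicted survival delegates to the LOEPIV survival function", {
  d <- reg_fixture(n = 200, censor_level = 0.1, seed = 81)
  fit <- withr::with_seed(5, loepiv_reg(survival::Surv(time, status) ~ x1,
                                        data = d))
  grid <- seq(-6, 4, length.out = 50)
  pr <- predict(fit, newdata = tibble::tibble(x1 = 0.5), log_time = grid)
  expect_true(all(diff(pr$survival) <= 1e-12))
  expect_equal(pr$survival,
               ploepiv(grid, fit$lambda, fit$alpha, fit$sigma,
                       mu = sum(fit$coefficients * c(1, 0.5)),
                       lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(predict(fit, tibble::tibble(x1 = 0), log_time = -50)$survival,
               1, tolerance = 1e-10)
  expect_lt(predict(fit, tibble::tibble(x1 = 0), log_time = 40)$survival,
            1e-10)
  expect_error(predict(fit, tibble::tibble(bad = 1), log_time = 0))
})

test_that("jackknife pseudo-values equal a literal drop-one refit loop", {
  # small uncensored sample where the maximum is interior and stable, so
  # two independent optimizer paths reach the same deletion estimates
  n <- 40
  d <- reg_fixture(n = n, censor_level = 0, seed = 93)
  fit <- withr::with_seed(6, loepiv_reg(survival::Surv(time, status) ~ x1,
                                        data = d))
  expect_false(fit$boundary)
  jk <- withr::with_seed(7, loepiv_jackknife(fit))
  expect_equal(jk$n_failed, 0)
  theta <- coef(fit)
  # independent brute-force loop through the public interface
  pseudo_oracle <- t(vapply(seq_len(n), function(i) {
    fi <- withr::with_seed(6,
      loepiv_reg(survival::Surv(time, status) ~ x1, data = d[-i, ],
                 init = fit$psi))
    n * theta - (n - 1) * coef(fi)
  }, numeric(5)))
  expect_lt(max(abs(unname(jk$pseudo_values) - unname(pseudo_oracle))),
            0.05)
  expect_equal(jk$estimate, colMeans(jk$pseudo_values), tolerance = 1e-12)
  se_oracle <- sqrt(colSums(sweep(jk$pseudo_values, 2,
                                  jk$estimate)^2) / (n * (n - 1)))
  expect_equal(unname(jk$std_errors), unname(se_oracle), tolerance = 1e-12)
  # positive parameters have their confidence bounds floored at zero
  expect_true(all(jk$ci_lower[c("sigma", "lambda", "alpha")] >= 0))
})

test_that("jackknife and ML estimates concord on well-specified data", {
  d <- reg_fixture(n = 80, censor_level = 0.1, seed = 104)
  fit <- withr::with_seed(8, loepiv_reg(survival::Surv(time, status) ~ x1,
                                        data = d))
  expect_false(fit$boundary)
  jk <- withr::with_seed(9, loepiv_jackknife(fit))
  expect_true(all(abs(jk$estimate - coef(fit)) <= fit$std_errors))
  td <- tidy(jk)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high"))
})
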