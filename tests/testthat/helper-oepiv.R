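# Shared fixtures: the two parameter sets of the estimator study and a
# generator of random valid parameter vectors.

set_1 <- c(lambda = 0.3, a = 0.4, theta = 0.5, alpha = 0.2)
set_2 <- c(lambda = 0.2, a = 0.1, theta = 0.6, alpha = 0.15)

random_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      lambda = exp(stats::runif(n, -1.5, 1.5)),
      a = exp(stats::runif(n, -1.5, 1)),
      theta = exp(stats::runif(n, -1, 1)),
      alpha = exp(stats::runif(n, -1.5, 1))
    )
  })
}

# numeric central-difference gradient, independent of the analytic score
num_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h * max(abs(x[i]), 1))
    (fn(x + e) - fn(x - e)) / (2 * e[i])
  }, numeric(1))
}

# small regression dataset from the censored design used across tests
reg_fixture <- function(n = 150, censor_level = 0.1, seed = 21) {
  simulate_loepiv_reg(n, lambda = 0.3, alpha = 0.36, sigma = 0.6,
                      beta0 = -0.6, beta1 = 1,
                      censor_level = censor_level, seed = seed)
}
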