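#' Case-deletion influence measures for a LOEPIV regression
#'
#' Computes, for every observation, the generalized Cook distance
#' \eqn{GD_i = (\hat\theta_{-i} - \hat\theta)^T J(\hat\theta)
#' (\hat\theta_{-i} - \hat\theta)} (quadratic form of the deletion
#' displacement in the observed-information metric, evaluated on the
#' natural parameter scale) and the likelihood distance
#' \eqn{LD_i = 2\{\ell(\hat\theta) - \ell(\hat\theta_{-i})\}}, where
#' \eqn{\ell(\hat\theta_{-i})} is the full-data log-likelihood evaluated at
#' the deletion estimate. Cases whose GD or LD exceeds the mean plus three
#' standard deviations of its vector are flagged as influential.
#'
#' @param fit A converged `loepiv_reg` fit.
#' @param loo Optional precomputed deletion estimates from [loepiv_loo()].
#' @return A tibble of class `loepiv_influence` with columns `case`, `gd`,
#'   `ld` and `flagged`; failed refits yield `NA` rows and are counted in
#'   the `n_failed` attribute.
#' @export
loepiv_influence <- function(fit, loo = NULL) {
  stopifnot(inherits(fit, "loepiv_reg"))
  if (is.null(loo)) loo <- loepiv_loo(fit)
  theta <- .theta_hat(fit)
  p <- ncol(fit$X)
  ll_at <- function(th) {
    loepiv_censored_loglik(fit$y, fit$status, fit$X, th[seq_len(p)],
                           th[p + 1], th[p + 2], th[p + 3])
  }
  # central-difference steps must keep sigma, lambda, alpha positive
  step <- 1e-4 * (1 + abs(theta))
  pos <- (p + 1):(p + 3)
  step[pos] <- pmin(step[pos], theta[pos] / 4)
  J <- -.num_hessian(function(th) {
    tryCatch(ll_at(th), error = function(e) NaN)
  }, theta, step = step)
  if (any(!is.finite(J))) {
    stop("observed information could not be evaluated at the estimate ",
         "(likelihood non-finite near it).", call. = FALSE)
  }
  ev <- eigen((J + t(J)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    warning("observed information at the full-sample estimate is not ",
            "positive definite; Cook distances are reported but may be ",
            "negative.", call. = FALSE)
  }
  ll_hat <- fit$loglik
  n <- fit$n
  gd <- ld <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(loo[i, ])) next
    d <- loo[i, ] - theta
    gd[i] <- drop(d %*% J %*% d)
    ld[i] <- 2 * (ll_hat - ll_at(loo[i, ]))
  }
  thr <- function(v) {
    v > mean(v, na.rm = TRUE) + 3 * stats::sd(v, na.rm = TRUE)
  }
  out <- tibble::tibble(case = seq_len(n), gd = gd, ld = ld,
                        flagged = thr(gd) | thr(ld))
  attr(out, "n_failed") <- sum(!stats::complete.cases(loo))
  class(out) <- c("loepiv_influence", class(out))
  out
}

#' @method autoplot loepiv_influence
#' @export
autoplot.loepiv_influence <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("gd", "ld"),
                              names_to = "measure", values_to = "value")
  long$measure <- dplyr::recode(long$measure,
                                gd = "generalized Cook distance",
                                ld = "likelihood distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$case, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$case, yend = 0),
                          colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25",
                                            `TRUE` = "#B2182B")) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "case index", y = NULL)
}

#' Martingale and deviance residuals of a LOEPIV regression
#'
#' Martingale residuals are \eqn{r_{M_i} = \delta_i + \log
#' S(y_i;\hat\theta)} with range \eqn{(-\infty, 1]}; deviance residuals are
#' the skewness-reducing transform \eqn{r_{D_i} = \mathrm{sign}(r_{M_i})
#' \sqrt{-2[r_{M_i} + \delta_i \log(\delta_i - r_{M_i})]}}, which for
#' censored cases reduces to \eqn{\mathrm{sign}(r_{M_i})\sqrt{-2 r_{M_i}}}.
#' Under a well-specified model the deviance residuals are approximately
#' standard normal.
#'
#' @param object A converged `loepiv_reg` fit.
#' @param type `"martingale"` or `"deviance"`.
#' @param ... Unused.
#' @return A numeric vector of residuals.
#' @export
residuals.loepiv_reg <- function(object,
                                 type = c("martingale", "deviance"), ...) {
  type <- match.arg(type)
  z <- (object$y - drop(object$X %*% object$coefficients)) / object$sigma
  lsf <- -object$lambda * expm1(object$alpha * .softplus(z))
  rM <- object$status + lsf
  if (type == "martingale") return(rM)
  d <- object$status
  arg <- -2 * (rM + d * log(d - rM))
  if (any(arg < -1e-8, na.rm = TRUE)) {
    stop("negative argument under the deviance square root at case(s) ",
         paste(utils::head(which(arg < -1e-8), 5), collapse = ", "),
         call. = FALSE)
  }
  sign(rM) * sqrt(pmax(arg, 0))
}

#' @method augment loepiv_reg
#' @export
augment.loepiv_reg <- function(x, ...) {
  mu <- drop(x$X %*% x$coefficients)
  tibble::tibble(
    y = x$y,
    status = x$status,
    .fitted = mu,
    .z = (x$y - mu) / x$sigma,
    .martingale = residuals(x, type = "martingale"),
    .deviance = residuals(x, type = "deviance")
  )
}

#' Kaplan-Meier survival curve as a tibble
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' estimate in rectangular form, convenient for overlay plots against a
#' fitted parametric survival curve.
#'
#' @param data A data frame with time and status columns.
#' @param time,status Column names (bare or string) of the observation time
#'   and the 0/1 event indicator.
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @examples
#' km_curve(data.frame(time = c(1, 2, 3), status = 1))
#' @export
km_curve <- function(data, time = time, status = status) {
  tcol <- rlang::as_name(rlang::enquo(time))
  scol <- rlang::as_name(rlang::enquo(status))
  df <- data.frame(.t = data[[tcol]],
                   .s = if (scol %in% names(data)) data[[scol]] else 1)
  if (any(df$.t <= 0)) stop("times must be positive.", call. = FALSE)
  sf <- survival::survfit(survival::Surv(.t, .s) ~ 1, data = df)
  tibble::tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 n_censor = sf$n.censor, survival = sf$surv)
}

#' Simulated envelope for deviance residuals
#'
#' Builds an Atkinson-style envelope for the normal probability plot of the
#' deviance residuals: `n_sim` datasets are simulated from the fitted model
#' (same design matrix, conditioning on the observed censoring pattern:
#' censored rows keep their observed censoring time, event rows are left
#' uncensored), each is refitted
#' and its ordered deviance residuals collected; per-rank percentile bands
#' are returned together with the observed ordered residuals.
#'
#' @param fit A converged `loepiv_reg` fit.
#' @param n_sim Number of simulated datasets (at least 19).
#' @param level Envelope coverage level (default 0.95, i.e. 2.5/97.5
#'   percentile bands per rank).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `loepiv_envelope` with columns `rank`,
#'   `theoretical` (standard normal quantiles), `observed`, `lower`,
#'   `median`, `upper`; failed refits are excluded and counted in the
#'   `n_failed` attribute.
#' @export
simulated_envelope <- function(fit, n_sim = 100, level = 0.95,
                               seed = NULL) {
  stopifnot(inherits(fit, "loepiv_reg"))
  if (!fit$converged) stop("fit did not converge.", call. = FALSE)
  if (n_sim < 19) stop("`n_sim` must be at least 19.", call. = FALSE)
  run <- function() {
    n <- fit$n
    mu <- drop(fit$X %*% fit$coefficients)
    # condition on the observed censoring pattern: a censored row keeps its
    # observed censoring time, an event row is left uncensored (its
    # censoring time is only known to exceed the event time)
    cens_time <- ifelse(fit$status == 0, fit$y, Inf)
    sims <- matrix(NA_real_, n, n_sim)
    for (s in seq_len(n_sim)) {
      ystar <- mu + fit$sigma * rloepiv_err(n, fit$lambda, fit$alpha)
      sstar <- as.numeric(ystar <= cens_time)
      ystar <- pmin(ystar, cens_time)
      core <- .reg_fit_core(ystar, sstar, fit$X, fit$psi, n_restarts = 1,
                            polish = FALSE)
      # boundary refits degenerate to the threshold limit, where events
      # below the fitted location have martingale residual exactly 1 and
      # the deviance transform diverges; they are excluded and counted
      if (!core$converged || core$boundary) next
      p <- ncol(fit$X)
      tmp <- fit
      tmp$y <- ystar; tmp$status <- sstar
      tmp$coefficients[] <- core$psi[seq_len(p)]
      tmp$sigma <- exp(core$psi[p + 1])
      tmp$lambda <- exp(core$psi[p + 2])
      tmp$alpha <- exp(core$psi[p + 3])
      rd <- tryCatch(residuals(tmp, type = "deviance"),
                     error = function(e) NULL)
      if (!is.null(rd) && all(is.finite(rd))) sims[, s] <- sort(rd)
    }
    sims
  }
  sims <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())
  ok <- colSums(is.na(sims)) == 0
  if (sum(ok) < 10) stop("too many envelope refits failed.", call. = FALSE)
  sims <- sims[, ok, drop = FALSE]
  alpha2 <- (1 - level) / 2
  out <- tibble::tibble(
    rank = seq_len(fit$n),
    theoretical = stats::qnorm(stats::ppoints(fit$n)),
    observed = sort(residuals(fit, type = "deviance")),
    lower = apply(sims, 1, stats::quantile, probs = alpha2),
    median = apply(sims, 1, stats::median),
    upper = apply(sims, 1, stats::quantile, probs = 1 - alpha2)
  )
  attr(out, "n_failed") <- sum(!ok)
  class(out) <- c("loepiv_envelope", class(out))
  out
}

#' @method autoplot loepiv_envelope
#' @export
autoplot.loepiv_envelope <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$theoretical)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "grey55",
                       linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 1.2) +
    ggplot2::labs(x = "standard normal quantiles",
                  y = "ordered deviance residuals",
                  title = "Normal probability plot with simulated envelope")
}
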