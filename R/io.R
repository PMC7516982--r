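#' Read a delimited survival table
#'
#' Reads a comma- or tab-delimited text file (delimiter sniffed from the
#' header line) with one row per subject, validates the required roles and
#' returns a tibble. Times must be strictly positive, the status indicator
#' 0/1 (1 = event, 0 = right-censored), covariates numeric, and no missing
#' values are allowed in required columns; violations raise errors naming
#' the offending row and column.
#'
#' @param path Path to the file.
#' @param time,status Names of the time and status columns.
#' @param covariates Optional character vector of covariate column names;
#'   defaults to every remaining numeric column.
#' @param status_flip If `TRUE`, the status coding is inverted on read
#'   (for files coded 0 = event, 1 = censored).
#' @return A tibble with the time and status columns first.
#' @export
read_survival_table <- function(path, time = "time", status = "status",
                                covariates = NULL, status_flip = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c(time, status)) {
    if (!col %in% names(df)) {
      stop("required column `", col, "` not found in ", path, call. = FALSE)
    }
    if (!is.numeric(df[[col]])) {
      stop("column `", col, "` is not numeric.", call. = FALSE)
    }
    if (anyNA(df[[col]])) {
      stop("column `", col, "` has missing values at row(s) ",
           paste(utils::head(which(is.na(df[[col]])), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (status_flip) df[[status]] <- 1 - df[[status]]
  bad_t <- which(df[[time]] <= 0)
  if (length(bad_t)) {
    stop("non-positive times in column `", time, "` at row(s) ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  }
  bad_s <- which(!df[[status]] %in% c(0, 1))
  if (length(bad_s)) {
    stop("status values outside {0, 1} in column `", status,
         "` at row(s) ", paste(utils::head(bad_s, 5), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(covariates)) {
    rest <- setdiff(names(df), c(time, status))
    covariates <- rest[vapply(df[rest], is.numeric, logical(1))]
  } else {
    missing_cov <- setdiff(covariates, names(df))
    if (length(missing_cov)) {
      stop("covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    for (col in covariates) {
      if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
        stop("covariate `", col, "` must be numeric with no missing ",
             "values.", call. = FALSE)
      }
    }
  }
  tibble::as_tibble(df[, c(time, status, covariates), drop = FALSE])
}

#' Write a survival table to delimited text
#'
#' @param x A data frame.
#' @param path Output path; `.tsv` extension writes tab-delimited,
#'   anything else comma-delimited.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic survival fixtures
#'
#' Reproducible synthetic datasets with known ground truth for testing and
#' demonstration:
#' * `"oepiv_sample"`: an uncensored OEPIV sample (defaults to the Set I
#'   parameters \eqn{\lambda=0.3, a=0.4, \theta=0.5, \alpha=0.2} of the
#'   estimator study) as a one-column `time` tibble;
#' * `"regression_sample"`: the censored regression design (defaults
#'   \eqn{\lambda=0.3, \alpha=0.36, \sigma=0.6, \beta_0=-0.6, \beta_1=1},
#'   uniform covariate, uniform censoring at `censor_level`);
#' * `"stanford_like"`: a purely synthetic table mimicking the schema of a
#'   heart-transplant registry — columns `time`, `status`, `age`
#'   (uniform on 8-64 years), binary `surgery` and `transplant` — with
#'   times generated from a LOEPIV regression; it shares only the schema,
#'   not the values, of any real registry.
#'
#' @param kind Fixture kind (see above).
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param ... Overrides of the generating parameters (`lambda`, `a`/`alpha`,
#'   `theta`/`sigma`, `beta0`, `beta1`, `censor_level`).
#' @return A tibble; the generating parameters are stored in the `truth`
#'   attribute.
#' @export
generate_fixture <- function(kind = c("oepiv_sample", "regression_sample",
                                      "stanford_like"),
                             n = 100, seed = 1, ...) {
  kind <- match.arg(kind)
  dots <- list(...)
  arg <- function(name, default) {
    if (!is.null(dots[[name]])) dots[[name]] else default
  }
  if (kind == "oepiv_sample") {
    pars <- c(lambda = arg("lambda", 0.3), a = arg("a", 0.4),
              theta = arg("theta", 0.5), alpha = arg("alpha", 0.2))
    out <- tibble::tibble(time = roepiv(n, pars[1], pars[2], pars[3],
                                        pars[4], seed = seed))
    attr(out, "truth") <- as.list(pars)
    return(out)
  }
  if (kind == "regression_sample") {
    return(simulate_loepiv_reg(
      n, lambda = arg("lambda", 0.3), alpha = arg("alpha", 0.36),
      sigma = arg("sigma", 0.6), beta0 = arg("beta0", -0.6),
      beta1 = arg("beta1", 1), censor_level = arg("censor_level", 0.3),
      seed = seed))
  }
  # stanford_like: synthetic table sharing only the registry schema
  truth <- list(lambda = arg("lambda", 1.4), alpha = arg("alpha", 0.13),
                sigma = arg("sigma", 0.56),
                beta = c(3.5, -0.054, 1.75, 2.54))
  gen <- function() {
    age <- stats::runif(n, 8, 64)
    surgery <- stats::rbinom(n, 1, 0.3)
    transplant <- stats::rbinom(n, 1, 0.65)
    mu <- truth$beta[1] + truth$beta[2] * age + truth$beta[3] * surgery +
      truth$beta[4] * transplant
    t <- exp(mu + truth$sigma * rloepiv_err(n, truth$lambda, truth$alpha))
    cc <- stats::runif(n, 0, stats::quantile(t, 0.9) * 2)
    tibble::tibble(time = pmin(t, cc), status = as.numeric(t <= cc),
                   age = age, surgery = surgery, transplant = transplant)
  }
  out <- withr::with_seed(as.integer(seed), gen())
  attr(out, "truth") <- truth
  out
}

#' Serialize parameter vectors and fits to JSON
#'
#' `write_params()`/`read_params()` round-trip a flat key-value parameter
#' configuration (keys `lambda`, `a`, `theta`, `alpha` on the natural
#' scale, or `lambda`, `alpha`, `sigma`, `mu` on the log scale) with full
#' double precision. `write_fit_json()` serializes an `oepiv_fit` or
#' `loepiv_reg` object (estimates, standard errors, information criteria).
#'
#' @param params A named list or vector of parameter values.
#' @param path File path.
#' @return `read_params()` a named list; the writers return `path`
#'   invisibly.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(as.list(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(out, as.numeric)
}

#' @rdname write_params
#' @param fit An `oepiv_fit` or `loepiv_reg` object.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "oepiv_fit")) {
    list(model = "oepiv",
         estimates = as.list(fit$estimates),
         std_errors = as.list(fit$std_errors),
         loglik = fit$loglik, aic = fit$aic, caic = fit$caic,
         bic = fit$bic, n = fit$n, converged = fit$converged)
  } else if (inherits(fit, "loepiv_reg")) {
    list(model = "loepiv_regression",
         beta = as.list(fit$coefficients),
         sigma = fit$sigma, lambda = fit$lambda, alpha = fit$alpha,
         std_errors = as.list(fit$std_errors),
         p_values = as.list(fit$p_values),
         loglik = fit$loglik, aic = fit$aic, caic = fit$caic,
         bic = fit$bic, n = fit$n, n_events = fit$n_events,
         converged = fit$converged)
  } else {
    stop("unsupported fit object.", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
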