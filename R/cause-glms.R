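# Prior-penalized logistic models of cause-specific infant mortality as
# a function of maternal age, and the decomposition of infant deaths
# into causes across maternal-age tertiles. Each cause is fit as an
# independent binary model (died of this cause vs. did not) on the
# fate-known dataset: infants censored before age one are removed.

.cause_levels <- c("maternal_death", "infanticide", "injury_or_illness",
                   "unknown")

.fate_known <- function(infants) {
  infants[infants$died | infants$time_observed >= 1, , drop = FALSE]
}

#' Fit a cause-specific infant-mortality logistic model
#'
#' MAP logistic regression of "died of `cause` in the first year" on
#' standardized maternal age and its square, with normal(0, 1) priors on
#' the age coefficients (weakly informative), an unpenalized (flat)
#' intercept, and optional birth-year intercepts as
#' Gaussian-penalized offsets whose standard deviation is profiled on a
#' coarse grid. The dataset is restricted to infants with known fates
#' (deaths, or survival to age one).
#'
#' @param infants an `infant_data` data frame.
#' @param cause one of `"maternal_death"`, `"infanticide"`,
#'   `"injury_or_illness"`, `"unknown"`.
#' @param prior_sd prior sd for the age coefficients (`Inf` gives the
#'   unpenalized MLE).
#' @param year_effects include penalized birth-year offsets.
#' @param sigma_grid profile grid for the year-offset sd.
#' @return Object of class `cause_fit` with elements `beta`
#'   (intercept, age, age2), `se`, `vcov`, `year_offsets`, `loglik`,
#'   `n_cases`, `n_total`, `scaling`, `degenerate`.
#' @export
fit_cause_model <- function(infants, cause = .cause_levels,
                            prior_sd = 1, year_effects = TRUE,
                            sigma_grid = exp(seq(log(0.05), log(2),
                                                 length.out = 10))) {
  cause <- match.arg(cause)
  d <- .fate_known(infants)
  if (!nrow(d)) stop("no fate-known infants", call. = FALSE)
  y <- as.integer(d$died & !is.na(d$cause) & d$cause == cause)
  degenerate <- sum(y) == 0 || sum(y) == length(y)
  if (degenerate) {
    warning("degenerate outcome for cause '", cause,
            "': estimates are prior-dominated")
  }

  center <- mean(d$maternal_age_at_birth)
  scale <- stats::sd(d$maternal_age_at_birth)
  if (!is.finite(scale) || scale == 0) scale <- 1
  z <- (d$maternal_age_at_birth - center) / scale
  X <- cbind(intercept = 1, age = z, age2 = z^2)
  prior <- c(Inf, prior_sd, prior_sd)  # flat prior on the intercept

  years <- if (year_effects) factor(d$birth_year) else factor(character(nrow(d)))
  G <- nlevels(years)
  use_years <- year_effects && G > 1

  negpost <- function(par, sigma) {
    beta <- par[1:3]
    eta <- drop(X %*% beta)
    if (use_years) eta <- eta + par[3 + as.integer(years)]
    ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
                (1 - y) * stats::plogis(-eta, log.p = TRUE))
    pen <- sum(ifelse(is.finite(prior), beta^2 / (2 * prior^2), 0))
    if (use_years) {
      b <- par[-(1:3)]
      pen <- pen + sum(b^2) / (2 * sigma^2) + length(b) * log(sigma)
    }
    -ll + pen
  }

  npar <- 3 + if (use_years) G else 0
  fit_at <- function(sigma) {
    stats::optim(numeric(npar), negpost, sigma = sigma, method = "BFGS",
                 hessian = FALSE, control = list(maxit = 500, reltol = 1e-10))
  }
  if (use_years) {
    fits <- lapply(sigma_grid, fit_at)
    k <- which.min(vapply(fits, `[[`, numeric(1), "value"))
    best <- fits[[k]]; sigma <- sigma_grid[k]
  } else {
    best <- fit_at(1); sigma <- NULL
  }

  hess <- stats::optimHess(best$par, negpost, sigma = sigma %||% 1)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, npar) else sqrt(pmax(diag(vc), 0))

  structure(list(cause = cause,
                 beta = stats::setNames(best$par[1:3],
                                        c("intercept", "age", "age2")),
                 se = stats::setNames(se[1:3], c("intercept", "age", "age2")),
                 vcov = vc,
                 year_offsets = if (use_years)
                   stats::setNames(best$par[-(1:3)], levels(years)) else NULL,
                 sigma_year = sigma,
                 loglik = -negpost(best$par, sigma %||% 1),
                 n_cases = sum(y), n_total = length(y),
                 prior_sd = prior_sd,
                 scaling = c(center = center, scale = scale),
                 degenerate = degenerate,
                 converged = best$convergence == 0),
            class = "cause_fit")
}

#' Fit all four cause-specific models
#'
#' @inheritParams fit_cause_model
#' @return Named list of `cause_fit` objects.
#' @export
fit_cause_models <- function(infants, prior_sd = 1, year_effects = TRUE) {
  stats::setNames(lapply(.cause_levels, function(cc)
    suppressWarnings(fit_cause_model(infants, cc, prior_sd, year_effects))),
    .cause_levels)
}

#' @export
print.cause_fit <- function(x, ...) {
  cat(sprintf("Cause-specific infant-mortality model: %s\n", x$cause))
  cat(sprintf("  %d cases / %d fate-known infants\n", x$n_cases, x$n_total))
  tab <- cbind(estimate = x$beta, se = x$se)
  print(round(tab, 4))
  if (x$degenerate) cat("  (degenerate outcome; prior-dominated)\n")
  invisible(x)
}

#' @export
coef.cause_fit <- function(object, ...) object$beta

#' Decompose infant deaths into causes across maternal-age tertiles
#'
#' Per-cause proportions of first-year deaths, overall and within
#' tertiles of maternal age at birth. Tertile boundaries are the
#' empirical terciles of maternal age among all infants in the dataset
#' (not only deaths); ages equal to a boundary fall in the lower
#' tertile.
#'
#' @param infants an `infant_data` data frame.
#' @return Object of class `mortality_decomposition`: list with
#'   `overall` (named proportions over the four causes), `by_tertile`
#'   (4 x 3 matrix of within-tertile proportions), `deaths_by_tertile`,
#'   `boundaries`, `n_deaths`.
#' @export
mortality_decomposition <- function(infants) {
  if (length(unique(infants$maternal_age_at_birth)) < 3) {
    stop("need at least 3 distinct maternal ages for tertiles",
         call. = FALSE)
  }
  q <- stats::quantile(infants$maternal_age_at_birth, c(1/3, 2/3),
                       names = FALSE)
  tert <- 1L + (infants$maternal_age_at_birth > q[1]) +
    (infants$maternal_age_at_birth > q[2])
  deaths <- infants$died & !is.na(infants$cause) &
    infants$cause %in% .cause_levels
  if (!any(deaths)) stop("no fate-known deaths", call. = FALSE)

  cause <- factor(infants$cause[deaths], levels = .cause_levels)
  tert_d <- tert[deaths]
  overall <- table(cause) / sum(deaths)
  by_tert <- vapply(1:3, function(k) {
    n <- sum(tert_d == k)
    if (n == 0) rep(NA_real_, 4) else
      as.numeric(table(cause[tert_d == k]) / n)
  }, numeric(4))
  dimnames(by_tert) <- list(.cause_levels, paste0("tertile", 1:3))

  structure(list(overall = stats::setNames(as.numeric(overall),
                                           .cause_levels),
                 by_tertile = by_tert,
                 deaths_by_tertile = tabulate(tert_d, 3),
                 boundaries = q, n_deaths = sum(deaths)),
            class = "mortality_decomposition")
}

#' @export
print.mortality_decomposition <- function(x, ...) {
  cat(sprintf("Infant-mortality cause decomposition (%d deaths)\n",
              x$n_deaths))
  cat("Overall proportions:\n")
  print(round(x$overall, 3))
  cat(sprintf("By maternal-age tertile (boundaries %.2f, %.2f yr):\n",
              x$boundaries[1], x$boundaries[2]))
  print(round(x$by_tertile, 3))
  invisible(x)
}
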