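# Proportional-hazards survival models with an M-spline baseline hazard,
# right censoring, delayed entry, quadratic maternal-age effects and —
# for interbirth intervals, where proportionality fails — time-varying
# age effects expressed on a coefficient B-spline basis. Fitting is by
# penalized maximum likelihood (MAP under independent Gaussian priors),
# with optional Gaussian-penalized random intercepts.
#
# Hazard: h(t | x) = h0(t) exp(eta(t, x)),   h0(t) = sum_i w_i M_i(t)
# with w_i >= 0 (log-parameterized). For constant effects the cumulative
# hazard is closed-form through the I-spline basis; for time-varying
# effects it is computed by Gauss-Legendre quadrature on each record's
# risk interval [t0, t].

#' Specify a spline-baseline hazard model
#'
#' @param age_effect `"quadratic"` (linear + quadratic terms, default),
#'   `"linear"`, or `"none"`.
#' @param tve logical; give the age terms time-varying coefficients
#'   \eqn{\beta(t)} on a B-spline basis (used when the proportional
#'   hazards assumption fails).
#' @param baseline_degree M-spline degree of the baseline hazard
#'   (default cubic).
#' @param baseline_knots internal knots for the baseline; `NULL` places
#'   them at the 33rd/67th percentiles of uncensored event times.
#' @param boundary_knots length-2 support of the baseline; `NULL` uses
#'   the minimum entry time and maximum observed time.
#' @param tve_degree,tve_knots coefficient-spline degree and internal
#'   knots; `NULL` puts one knot at the median event time.
#' @param random_intercepts character vector of grouping columns
#'   (subset of `"mother"`, `"year"`, `"unit"`) given Gaussian-penalized
#'   per-group offsets; `NULL` (default) fits fixed effects only.
#' @param age_scaling `"standardize"` (default; center/scale age to mean
#'   0, sd 1 before the polynomial expansion) or `"none"`.
#' @param prior_sd_coef prior standard deviation for covariate and
#'   time-varying coefficients (`Inf` disables the penalty, giving plain
#'   maximum likelihood).
#' @param prior_sd_logweight prior standard deviation for log baseline
#'   weights (`Inf` disables).
#' @param n_quad Gauss-Legendre nodes per record for time-varying
#'   cumulative hazards.
#' @return Object of class `hazard_model_spec`.
#' @export
hazard_model_spec <- function(age_effect = c("quadratic", "linear", "none"),
                              tve = FALSE, baseline_degree = 3,
                              baseline_knots = NULL, boundary_knots = NULL,
                              tve_degree = 2, tve_knots = NULL,
                              random_intercepts = NULL,
                              age_scaling = c("standardize", "none"),
                              prior_sd_coef = 2.5, prior_sd_logweight = 5,
                              n_quad = 15) {
  structure(list(age_effect = match.arg(age_effect), tve = tve,
                 baseline_degree = baseline_degree,
                 baseline_knots = baseline_knots,
                 boundary_knots = boundary_knots,
                 tve_degree = tve_degree, tve_knots = tve_knots,
                 random_intercepts = random_intercepts,
                 age_scaling = match.arg(age_scaling),
                 prior_sd_coef = prior_sd_coef,
                 prior_sd_logweight = prior_sd_logweight,
                 n_quad = n_quad),
            class = "hazard_model_spec")
}

# normalize the two analysis datasets (and plain data frames) to
# time/event/entry/age plus grouping columns
.hazard_data <- function(data) {
  if (inherits(data, "ibi_data")) {
    out <- data.frame(time = data$duration, event = data$closed,
                      entry = data$entry_offset,
                      age = data$maternal_age_at_start,
                      mother = data$mother_id,
                      year = as.character(data$study_year),
                      unit = data$unit_id, stringsAsFactors = FALSE)
  } else if (inherits(data, "infant_data")) {
    out <- data.frame(time = data$time_observed, event = data$died,
                      entry = 0, age = data$maternal_age_at_birth,
                      mother = data$mother_id,
                      year = as.character(data$birth_year),
                      unit = data$unit_id, stringsAsFactors = FALSE)
  } else {
    if (!all(c("time", "event") %in% names(data))) {
      stop("data must have 'time' and 'event' columns (or be ibi_data/infant_data)",
           call. = FALSE)
    }
    out <- as.data.frame(data)
    if (is.null(out$entry)) out$entry <- 0
    if (is.null(out$age)) out$age <- 0
  }
  if (any(out$time < out$entry)) {
    stop("observed times before the entry offset", call. = FALSE)
  }
  out
}

# workspace: bases, design matrices, parameter layout
.prepare_hazard <- function(spec, data) {
  d <- .hazard_data(data)
  n <- nrow(d)
  if (sum(d$event) < 1) stop("need at least one event", call. = FALSE)

  if (spec$age_scaling == "standardize") {
    center <- mean(d$age); scale <- stats::sd(d$age)
    if (!is.finite(scale) || scale == 0) scale <- 1
  } else {
    center <- 0; scale <- 1
  }
  z <- (d$age - center) / scale
  Xc <- switch(spec$age_effect,
               none = matrix(0, n, 0),
               linear = cbind(age = z),
               quadratic = cbind(age = z, age2 = z^2))

  ev_times <- d$time[d$event]
  boundary <- spec$boundary_knots
  if (is.null(boundary)) boundary <- c(min(d$entry), max(d$time))
  if (boundary[1] >= boundary[2]) boundary[2] <- boundary[1] + max(d$time, 1)
  internal <- spec$baseline_knots
  if (is.null(internal)) {
    internal <- unique(stats::quantile(ev_times, c(1/3, 2/3), names = FALSE))
    internal <- internal[internal > boundary[1] & internal < boundary[2]]
  }
  baseline <- mspline_basis(spec$baseline_degree, boundary, internal)

  tve_basis <- NULL
  if (spec$tve && ncol(Xc) > 0) {
    tknots <- spec$tve_knots
    if (is.null(tknots)) {
      tknots <- stats::median(ev_times)
      tknots <- tknots[tknots > boundary[1] & tknots < boundary[2]]
    }
    tve_basis <- bspline_basis(spec$tve_degree, boundary, tknots)
  }

  groups <- list()
  for (g in spec$random_intercepts %||% character(0)) {
    if (is.null(d[[g]])) stop("no grouping column '", g, "' in data",
                              call. = FALSE)
    groups[[g]] <- factor(d[[g]])
  }

  nb <- baseline$n_basis
  p <- ncol(Xc)
  nc <- if (is.null(tve_basis)) 0L else tve_basis$n_basis
  coef_per_cov <- if (nc > 0) nc else 1L
  n_coef <- p * coef_per_cov
  n_off <- sum(vapply(groups, nlevels, integer(1)))
  layout <- list(logw = seq_len(nb),
                 coef = nb + seq_len(n_coef),
                 off = nb + n_coef + seq_len(n_off))
  coef_names <- if (p == 0) character(0) else if (nc > 0) {
    as.vector(t(outer(colnames(Xc), paste0("s", seq_len(nc)), paste, sep = ":")))
  } else colnames(Xc)
  par_names <- c(paste0("logw", seq_len(nb)), coef_names,
                 unlist(lapply(names(groups), function(g)
                   paste0(g, ":", levels(groups[[g]])))))

  ws <- list(spec = spec, d = d, n = n, Xc = Xc, z = z,
             center = center, scale = scale,
             baseline = baseline, tve_basis = tve_basis,
             groups = groups, nb = nb, p = p, nc = nc,
             layout = layout, par_names = par_names,
             npar = nb + n_coef + n_off)

  # precomputed design pieces
  ev <- which(d$event)
  ws$ev <- ev
  ws$M_ev <- evaluate_basis(baseline, d$time[ev], "M")
  if (nc == 0) {
    ws$dI <- evaluate_basis(baseline, d$time, "I") -
      evaluate_basis(baseline, d$entry, "I")
  } else {
    gl <- gauss_legendre(spec$n_quad)
    half <- (d$time - d$entry) / 2
    mid <- (d$time + d$entry) / 2
    u <- as.vector(outer(gl$nodes, half) + rep(mid, each = spec$n_quad))
    ws$qw <- as.vector(outer(gl$weights, half))       # quadrature weights
    ws$qid <- rep(seq_len(n), each = spec$n_quad)     # owner record
    ws$M_q <- evaluate_basis(baseline, u, "M")
    ws$C_q <- evaluate_basis(tve_basis, u, "B")
    ws$C_ev <- evaluate_basis(tve_basis, d$time[ev], "B")
  }
  if (length(groups)) {
    ws$group_idx <- list()
    offset <- 0L
    for (g in names(groups)) {
      ws$group_idx[[g]] <- offset + as.integer(groups[[g]])
      offset <- offset + nlevels(groups[[g]])
    }
  }
  ws
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# record-level offsets from random-intercept parameters
.rec_offsets <- function(ws, b) {
  if (!length(ws$groups)) return(numeric(ws$n))
  out <- numeric(ws$n)
  for (g in names(ws$group_idx)) out <- out + b[ws$group_idx[[g]]]
  out
}

# negative log-likelihood (optionally + Gaussian penalties)
.hazard_nll <- function(ws, par, penalized = TRUE, sigma_re = 0.5) {
  w <- exp(par[ws$layout$logw])
  off <- .rec_offsets(ws, par[ws$layout$off])
  d <- ws$d

  if (ws$nc == 0) {
    beta <- par[ws$layout$coef]
    eta <- if (ws$p) drop(ws$Xc %*% beta) else numeric(ws$n)
    eta <- eta + off
    h0_ev <- drop(ws$M_ev %*% w)
    if (any(h0_ev <= 0)) return(Inf)
    ll <- sum(log(h0_ev) + eta[ws$ev]) - sum(exp(eta) * drop(ws$dI %*% w))
  } else {
    G <- matrix(par[ws$layout$coef], nrow = ws$nc)  # nc x p
    eta_ev <- rowSums((ws$C_ev %*% G) * ws$Xc[ws$ev, , drop = FALSE]) +
      off[ws$ev]
    h0_ev <- drop(ws$M_ev %*% w)
    if (any(h0_ev <= 0)) return(Inf)
    eta_q <- rowSums((ws$C_q %*% G) * ws$Xc[ws$qid, , drop = FALSE]) +
      off[ws$qid]
    Hq <- ws$qw * drop(ws$M_q %*% w) * exp(eta_q)
    ll <- sum(log(h0_ev) + eta_ev) - sum(Hq)
  }
  if (!is.finite(ll)) return(Inf)
  nll <- -ll
  if (penalized) {
    sp <- ws$spec
    if (is.finite(sp$prior_sd_logweight)) {
      nll <- nll + sum(par[ws$layout$logw]^2) / (2 * sp$prior_sd_logweight^2)
    }
    if (ws$p && is.finite(sp$prior_sd_coef)) {
      nll <- nll + sum(par[ws$layout$coef]^2) / (2 * sp$prior_sd_coef^2)
    }
    if (length(ws$layout$off)) {
      b <- par[ws$layout$off]
      nll <- nll + sum(b^2) / (2 * sigma_re^2) +
        length(b) * log(sigma_re)
    }
  }
  nll
}

#' Negative (penalized) log-likelihood of a hazard model
#'
#' The objective minimized by [fit_hazard_model()]: minus the
#' right-censored, delayed-entry log-likelihood
#' \eqn{\sum_{events} \log h(t_i|x_i) - \sum_i [H(t_i|x_i) - H(t_{0i}|x_i)]}
#' plus the Gaussian prior penalties of the spec. A nonpositive hazard at
#' an event time yields `Inf`, not an error.
#'
#' @param spec a `hazard_model_spec`.
#' @param params numeric parameter vector: log baseline weights, then
#'   covariate (or coefficient-spline) coefficients, then any
#'   random-intercept offsets.
#' @param data an `ibi_data`/`infant_data` object or a data frame with
#'   `time`, `event` and optional `entry`, `age` columns.
#' @param penalized include the prior penalties (default `TRUE`).
#' @return Scalar objective value.
#' @export
hazard_neg_loglik <- function(spec, params, data, penalized = TRUE) {
  ws <- .prepare_hazard(spec, data)
  if (length(params) != ws$npar) {
    stop(sprintf("params has length %d, model needs %d", length(params),
                 ws$npar), call. = FALSE)
  }
  .hazard_nll(ws, params, penalized = penalized)
}

.parscale <- function(ws) {
  parscale <- rep(1, ws$npar)
  if (ws$p > 0) {
    col_sd <- pmax(apply(ws$Xc, 2, stats::sd), 1e-3)
    parscale[ws$layout$coef] <- rep(1 / col_sd,
                                    each = length(ws$layout$coef) / ws$p)
  }
  parscale
}

.fit_once <- function(ws, start, sigma_re, maxit) {
  fn <- function(p) .hazard_nll(ws, p, penalized = TRUE, sigma_re = sigma_re)
  stats::optim(start, fn, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12,
                              parscale = .parscale(ws)))
}

#' Fit a spline-baseline hazard model by penalized maximum likelihood
#'
#' Fits \eqn{h(t|x) = h_0(t)\exp(\eta(t,x))} with an M-spline baseline
#' (log-parameterized weights for positivity), quadratic maternal-age
#' effects, optional time-varying coefficients, and optional
#' Gaussian-penalized random intercepts whose standard deviation is
#' profiled on a coarse grid. Optimization is multi-start BFGS with
#' jittered restarts under `seed`; standard errors come from the
#' observed-information matrix at the optimum.
#'
#' @param data an `ibi_data` or `infant_data` object (from
#'   [extract_intervals()] / [build_infant_dataset()]), or a data frame
#'   with `time`, `event`, optional `entry` and `age` columns.
#' @param spec a [hazard_model_spec()]; `...` is passed to
#'   `hazard_model_spec()` when `spec` is missing.
#' @param n_starts number of optimizer starts (first from a
#'   constant-hazard initializer, the rest jittered).
#' @param seed RNG seed for the jittered starts.
#' @param maxit BFGS iteration cap per start.
#' @param sigma_grid grid of random-intercept standard deviations to
#'   profile over (only used when the spec has random intercepts).
#' @param ... arguments forwarded to [hazard_model_spec()].
#' @return Object of class `hazard_fit`; see [print.hazard_fit()],
#'   [coef.hazard_fit()], [predict.hazard_fit()], [tve_coefficient()].
#' @examples
#' set.seed(1)
#' d <- data.frame(time = rexp(120, 0.6), event = TRUE,
#'                 age = rnorm(120))
#' fit <- fit_hazard_model(d, age_effect = "linear",
#'                         prior_sd_coef = Inf, prior_sd_logweight = Inf)
#' coef(fit)
#' @export
fit_hazard_model <- function(data, spec = NULL, n_starts = 5, seed = 1,
                             maxit = 400,
                             sigma_grid = exp(seq(log(0.05), log(2),
                                                  length.out = 10)),
                             ...) {
  if (is.null(spec)) spec <- hazard_model_spec(...)
  ws <- .prepare_hazard(spec, data)
  d <- ws$d

  # constant-hazard initializer: sum(w) = h * span
  h_const <- sum(d$event) / sum(d$time - d$entry)
  span <- diff(ws$baseline$boundary_knots)
  start0 <- numeric(ws$npar)
  start0[ws$layout$logw] <- log(h_const * span / ws$nb)

  set.seed(seed)
  jitter_scale <- 0.5 * .parscale(ws)
  starts <- lapply(seq_len(n_starts), function(s) {
    if (s == 1) start0 else start0 + stats::rnorm(ws$npar, 0, jitter_scale)
  })

  run_starts <- function(sigma_re) {
    best <- NULL
    for (st in starts) {
      res <- tryCatch(.fit_once(ws, st, sigma_re, maxit),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    best
  }

  if (length(ws$groups)) {
    # profile sigma on the grid by a Laplace-approximate marginal:
    # joint objective at the mode plus half the log-determinant of the
    # offset curvature (diagonal approximation); without the curvature
    # term the joint MAP over (offsets, sigma) degenerates to sigma -> 0
    fits <- lapply(sigma_grid, run_starts)
    vals <- vapply(seq_along(fits), function(k) {
      f <- fits[[k]]
      if (is.null(f)) return(Inf)
      off_idx <- ws$layout$off
      delta <- 1e-4
      fn <- function(p) .hazard_nll(ws, p, TRUE, sigma_grid[k])
      f0 <- f$value
      logdet <- sum(vapply(off_idx, function(j) {
        up <- f$par; up[j] <- up[j] + delta
        dn <- f$par; dn[j] <- dn[j] - delta
        log(max((fn(up) - 2 * f0 + fn(dn)) / delta^2, 1e-8))
      }, numeric(1)))
      f$value + 0.5 * logdet
    }, numeric(1))
    k <- which.min(vals)
    best <- fits[[k]]
    sigma_re <- sigma_grid[k]
  } else {
    best <- run_starts(0.5)
    sigma_re <- NULL
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  hess <- tryCatch(
    stats::optimHess(best$par, function(p)
      .hazard_nll(ws, p, penalized = TRUE, sigma_re = sigma_re %||% 0.5)),
    error = function(e) NULL)
  vc <- if (is.null(hess)) NULL else
    tryCatch(solve(hess), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, ws$npar) else {
    dg <- diag(vc)
    ifelse(dg > 0, sqrt(dg), NA_real_)
  }

  par <- stats::setNames(best$par, ws$par_names)
  beta <- if (ws$p == 0) numeric(0) else if (ws$nc > 0) {
    G <- matrix(par[ws$layout$coef], nrow = ws$nc,
                dimnames = list(NULL, colnames(ws$Xc)))
    G
  } else stats::setNames(par[ws$layout$coef], colnames(ws$Xc))

  structure(list(
    spec = spec, ws = ws,
    coefficients = par,
    baseline_weights = exp(par[ws$layout$logw]),
    beta = beta,
    se = stats::setNames(se, ws$par_names),
    vcov = vc,
    loglik = -.hazard_nll(ws, best$par, penalized = FALSE),
    penalized_objective = best$value,
    n = ws$n, n_events = sum(d$event), n_censored = sum(!d$event),
    converged = best$convergence == 0,
    sigma_re = sigma_re,
    age_scaling = c(center = ws$center, scale = ws$scale),
    baseline_basis = ws$baseline, tve_basis = ws$tve_basis,
    n_starts = n_starts, seed = seed), class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("Spline-baseline hazard model (penalized ML)\n")
  cat(sprintf("  records: %d (%d events, %d censored)\n", x$n, x$n_events,
              x$n_censored))
  cat(sprintf("  baseline: degree-%d M-spline, %d weights, support [%g, %g]\n",
              x$baseline_basis$degree, x$baseline_basis$n_basis,
              x$baseline_basis$boundary_knots[1],
              x$baseline_basis$boundary_knots[2]))
  if (!is.null(x$tve_basis)) {
    cat("  time-varying age effects on a coefficient B-spline basis\n")
  }
  if (!is.null(x$sigma_re)) {
    cat(sprintf("  random-intercept sd (profiled): %.3f\n", x$sigma_re))
  }
  cat(sprintf("  log-likelihood: %.3f%s\n", x$loglik,
              if (x$converged) "" else "  [optimizer did not converge]"))
  if (length(x$beta)) {
    cat("\nAge coefficients (standardized-age scale):\n")
    if (is.matrix(x$beta)) {
      print(round(x$beta, 4))
    } else {
      idx <- x$ws$layout$coef
      tab <- cbind(estimate = x$beta, se = x$se[idx])
      print(round(tab, 4))
    }
  }
  invisible(x)
}

#' @export
summary.hazard_fit <- function(object, ...) {
  idx <- c(object$ws$layout$logw, object$ws$layout$coef)
  tab <- data.frame(estimate = object$coefficients[idx],
                    se = object$se[idx])
  tab$z <- tab$estimate / tab$se
  structure(list(fit = object, table = tab), class = "summary.hazard_fit")
}

#' @export
print.summary.hazard_fit <- function(x, ...) {
  print(x$fit)
  cat("\nAll free parameters:\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.hazard_fit <- function(object, ...) object$beta

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$loglik, df = object$ws$npar, class = "logLik")
}

#' @export
vcov.hazard_fit <- function(object, ...) object$vcov

#' Baseline hazard of a fitted model
#'
#' @param fit a `hazard_fit`.
#' @param times evaluation grid.
#' @return Numeric vector \eqn{h_0(t)}.
#' @export
baseline_hazard <- function(fit, times) {
  drop(evaluate_basis(fit$baseline_basis, times, "M") %*% fit$baseline_weights)
}

# record-free eta machinery for prediction
.predict_H <- function(fit, z_age, times, entry) {
  ws <- fit$ws
  x_row <- switch(ws$spec$age_effect, none = numeric(0),
                  linear = z_age, quadratic = c(z_age, z_age^2))
  w <- fit$baseline_weights
  if (ws$nc == 0) {
    eta <- if (ws$p) sum(x_row * fit$beta) else 0
    dI <- evaluate_basis(fit$baseline_basis, times, "I") -
      matrix(evaluate_basis(fit$baseline_basis, entry, "I"),
             nrow = length(times), ncol = ws$nb, byrow = TRUE)
    exp(eta) * drop(dI %*% w)
  } else {
    gl <- gauss_legendre(ws$spec$n_quad)
    vapply(times, function(t1) {
      if (t1 <= entry) return(0)
      half <- (t1 - entry) / 2; mid <- (t1 + entry) / 2
      u <- mid + half * gl$nodes
      h0 <- drop(evaluate_basis(fit$baseline_basis, u, "M") %*% w)
      bt <- evaluate_basis(fit$tve_basis, u, "B") %*% fit$beta  # Q x p
      eta <- drop(bt %*% x_row)
      sum(half * gl$weights * h0 * exp(eta))
    }, numeric(1))
  }
}

#' Predicted survival curves from a fitted hazard model
#'
#' \eqn{S(t|x) = \exp\{-[H(t|x) - H(t_0|x)]\}} on the requested grid;
#' monotone nonincreasing in `t`. Times outside the baseline support are
#' clamped to it with a warning.
#'
#' @param object a `hazard_fit`.
#' @param age raw maternal age(s); standardized internally with the
#'   fit's scaling.
#' @param times evaluation grid (years).
#' @param entry entry (delayed-entry) time \eqn{t_0}; defaults to the
#'   smallest entry time in the fitted data.
#' @param ... unused.
#' @return Matrix of survival probabilities, rows = `times`,
#'   columns = `age` values.
#' @export
predict.hazard_fit <- function(object, age = NULL, times = NULL,
                               entry = NULL, ...) {
  bk <- object$baseline_basis$boundary_knots
  if (is.null(times)) times <- seq(bk[1], bk[2], length.out = 101)
  if (any(times < bk[1] | times > bk[2])) {
    warning("times outside the baseline support were clamped")
    times <- pmin(pmax(times, bk[1]), bk[2])
  }
  if (is.null(entry)) entry <- min(object$ws$d$entry)
  if (is.null(age)) age <- stats::median(object$ws$d$age)
  sc <- object$age_scaling
  out <- vapply(age, function(a) {
    z <- (a - sc["center"]) / sc["scale"]
    H <- .predict_H(object, z, times, entry)
    H0 <- .predict_H(object, z, entry, entry)
    exp(-(H - H0))
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times),
                dimnames = list(NULL, paste0("age=", signif(age, 4))))
  out
}

#' Martingale-type residuals
#'
#' `event - (H(t) - H(t0))` per record.
#'
#' @param object a `hazard_fit`.
#' @param ... unused.
#' @export
residuals.hazard_fit <- function(object, ...) {
  ws <- object$ws
  d <- ws$d
  sc <- object$age_scaling
  H <- vapply(seq_len(ws$n), function(i) {
    z <- (d$age[i] - sc["center"]) / sc["scale"]
    .predict_H(object, z, d$time[i], d$entry[i])
  }, numeric(1))
  as.numeric(d$event) - H
}

#' Time-varying age coefficient with pointwise standard errors
#'
#' Evaluates the fitted coefficient function \eqn{\beta_j(t)} (on the
#' standardized-age scale) over a time grid, with delta-method standard
#' errors from the observed-information matrix.
#'
#' @param fit a `hazard_fit` with time-varying effects.
#' @param covariate `"age"` or `"age2"`.
#' @param times evaluation grid; defaults to 101 points over the
#'   baseline support.
#' @return Data frame with `time`, `estimate`, `se`.
#' @export
tve_coefficient <- function(fit, covariate = "age", times = NULL) {
  ws <- fit$ws
  if (is.null(ws$tve_basis)) {
    stop("model was fitted without time-varying effects", call. = FALSE)
  }
  bk <- fit$baseline_basis$boundary_knots
  if (is.null(times)) times <- seq(bk[1], bk[2], length.out = 101)
  j <- match(covariate, colnames(ws$Xc))
  if (is.na(j)) stop("unknown covariate: ", covariate, call. = FALSE)
  C <- evaluate_basis(ws$tve_basis, times, "B")
  idx <- ws$layout$coef[(j - 1) * ws$nc + seq_len(ws$nc)]
  est <- drop(C %*% fit$coefficients[idx])
  se <- rep(NA_real_, length(times))
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[idx, idx, drop = FALSE]
    se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  }
  data.frame(time = times, estimate = est, se = se)
}

#' @export
plot.hazard_fit <- function(x, ages = NULL, times = NULL, ...) {
  d <- x$ws$d
  if (is.null(ages)) {
    ages <- stats::quantile(d$age, c(0.1, 0.5, 0.9), names = FALSE)
  }
  S <- predict(x, age = ages, times = times)
  bk <- x$baseline_basis$boundary_knots
  if (is.null(times)) times <- seq(bk[1], bk[2], length.out = 101)
  graphics::matplot(times, S, type = "l", lty = 1, lwd = 2,
                    col = c("darkorange", "grey40", "steelblue"),
                    xlab = "time (years)", ylab = "S(t)",
                    main = "Predicted survival by maternal age", ...)
  graphics::legend("topright", legend = paste("age", signif(ages, 3)),
                   col = c("darkorange", "grey40", "steelblue"), lwd = 2,
                   bty = "n")
  invisible(x)
}
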