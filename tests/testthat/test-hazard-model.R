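# spline-baseline hazard model: closed forms, bookkeeping, recovery

exp_spec <- function(tau, ...) {
  hazard_model_spec(age_effect = "none", baseline_degree = 0,
                    baseline_knots = numeric(0), boundary_knots = c(0, tau),
                    prior_sd_coef = Inf, prior_sd_logweight = Inf, ...)
}

test_that("degree-0 single span reduces to the exponential model", {
  set.seed(1)
  n <- 150
  tt <- rexp(n, 0.7)
  d <- data.frame(time = pmin(tt, 2), event = tt <= 2)
  fit <- fit_hazard_model(d, spec = exp_spec(2), n_starts = 2)
  h_closed <- sum(d$event) / sum(d$time)
  h_hat <- fit$baseline_weights / 2
  expect_equal(unname(h_hat), h_closed, tolerance = 1e-6)
  ll_closed <- sum(d$event) * log(h_closed) - h_closed * sum(d$time)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
  # survival matches the exponential closed form
  S <- predict(fit, age = 0, times = c(0, 0.7, 1.5))
  expect_equal(as.numeric(S), exp(-h_hat * c(0, 0.7, 1.5)),
               tolerance = 1e-8)
})

test_that("delayed entry removes exposure: entry = time leaves only event terms", {
  set.seed(2)
  d <- data.frame(time = rexp(30, 1) + 0.5, event = TRUE)
  d$entry <- d$time        # zero risk time
  spec <- exp_spec(5)
  params <- log(2 * 5)     # log total weight for h0 = 2
  # only sum(log h) remains: n * log(2)
  expect_equal(hazard_neg_loglik(spec, params, d, penalized = FALSE),
               -nrow(d) * log(2), tolerance = 1e-10)
  # with entry 0 the exposure term reappears
  d0 <- d; d0$entry <- 0
  expect_equal(hazard_neg_loglik(spec, params, d0, penalized = FALSE),
               -nrow(d) * log(2) + 2 * sum(d$time), tolerance = 1e-10)
})

test_that("all-censored data drives the penalized baseline towards zero", {
  d <- data.frame(time = runif(40, 1, 3), event = FALSE)
  d$event[1] <- TRUE       # one event keeps the fit defined
  fit <- fit_hazard_model(d, spec = hazard_model_spec(
    age_effect = "none", baseline_degree = 0, baseline_knots = numeric(0),
    boundary_knots = c(0, 3)), n_starts = 2)
  almost_censored <- sum(fit$baseline_weights) / 3
  d2 <- d; d2$event[2:10] <- TRUE
  fit2 <- fit_hazard_model(d2, spec = hazard_model_spec(
    age_effect = "none", baseline_degree = 0, baseline_knots = numeric(0),
    boundary_knots = c(0, 3)), n_starts = 2)
  expect_lt(almost_censored, sum(fit2$baseline_weights) / 3)
})

test_that("event/censoring bookkeeping always adds up", {
  sim <- simulate_population(sim_preset("chacma-like"), seed = 5)
  iv <- extract_intervals(sim$records)
  fit <- fit_hazard_model(iv, n_starts = 2, seed = 1)
  expect_identical(fit$n_events + fit$n_censored, nrow(iv))
  expect_identical(fit$n_events, sum(iv$closed))
  expect_true(is.finite(fit$loglik))
  expect_true(all(fit$baseline_weights >= 0))
})

test_that("null age effect is recovered as null", {
  set.seed(3)
  n <- 300
  tt <- rexp(n, 0.6)
  d <- data.frame(time = pmin(tt, 4), event = tt <= 4, age = rnorm(n))
  fit <- fit_hazard_model(d, spec = hazard_model_spec(age_scaling = "none"),
                          n_starts = 3, seed = 3)
  idx <- fit$ws$layout$coef
  expect_lt(abs(fit$beta["age"]), 2 * fit$se[idx[1]])
  expect_lt(abs(fit$beta["age2"]), 2 * fit$se[idx[2]])
})

test_that("fitted hazard on the raw-age scale is invariant to age scaling", {
  set.seed(4)
  n <- 400
  age <- runif(n, 6, 24)
  z <- (age - 15) / 5
  rate <- 0.4 * exp(0.3 * z - 0.2 * z^2)
  tt <- rexp(n, rate)
  d <- data.frame(time = pmin(tt, 4), event = tt <= 4, age = age)
  base <- hazard_model_spec(age_scaling = "standardize",
                            prior_sd_coef = Inf, prior_sd_logweight = Inf)
  none <- hazard_model_spec(age_scaling = "none",
                            prior_sd_coef = Inf, prior_sd_logweight = Inf)
  f1 <- fit_hazard_model(d, spec = base, n_starts = 3, seed = 1)
  f2 <- fit_hazard_model(d, spec = none, n_starts = 3, seed = 1)
  times <- seq(0.5, 3.5, 0.5)
  for (a in c(8, 15, 22)) {
    s1 <- predict(f1, age = a, times = times, entry = 0)
    s2 <- predict(f2, age = a, times = times, entry = 0)
    expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-3)
  }
})

test_that("predicted survival is one at entry and monotone nonincreasing", {
  sim <- simulate_population(sim_preset("gelada-like"), seed = 7)
  iv <- extract_intervals(sim$records)
  fit <- fit_hazard_model(iv, n_starts = 2, seed = 2)
  t0 <- iv$entry_offset[1]
  grid <- seq(t0, max(iv$duration), length.out = 80)
  S <- predict(fit, age = c(8, 12, 20), times = grid, entry = t0)
  expect_equal(as.numeric(S[1, ]), rep(1, 3))
  expect_true(all(diff(S[, 1]) <= 1e-10))
  expect_true(all(diff(S[, 2]) <= 1e-10))
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  expect_warning(predict(fit, age = 10, times = c(0, 100)), "clamped")
})

test_that("martingale residuals sum to near zero at the ML optimum", {
  set.seed(5)
  n <- 200
  tt <- rexp(n, 0.8)
  d <- data.frame(time = pmin(tt, 3), event = tt <= 3)
  fit <- fit_hazard_model(d, spec = exp_spec(3), n_starts = 2)
  r <- residuals(fit)
  expect_equal(length(r), n)
  expect_lt(abs(sum(r)), 1e-4)
})

test_that("random intercepts shrink towards zero and are profiled", {
  set.seed(6)
  n_g <- 15
  b <- rnorm(n_g, 0, 0.6)
  g <- rep(seq_len(n_g), each = 20)
  tt <- rexp(n_g * 20, 0.5 * exp(b[g]))
  d <- data.frame(time = pmin(tt, 5), event = tt <= 5,
                  mother = paste0("m", g))
  fit <- fit_hazard_model(d, spec = hazard_model_spec(
    age_effect = "none", random_intercepts = "mother"),
    n_starts = 2, seed = 1)
  offs <- fit$coefficients[paste0("mother:m", seq_len(n_g))]
  expect_true(fit$sigma_re > 0.05 && fit$sigma_re <= 2)
  # group offsets correlate with the true frailties
  expect_gt(cor(offs, b), 0.5)
  # and are shrunk relative to them
  expect_lt(stats::sd(offs), stats::sd(b) * 1.5)
})
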