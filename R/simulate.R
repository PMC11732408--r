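# Individual-based simulator of female primate life histories. Females
# die according to a Siler (bathtub) hazard, conceive via a thinned
# Poisson process with an inverted-U age effect, and give birth after a
# fixed gestation; male takeovers arrive per social unit as Poisson
# processes and kill dependent infants with a fixed probability within
# the 180 days that the attribution rules assume; infants whose mother
# dies face an orphaning death within 90 days. Every simulated death
# carries its true cause, so downstream attribution, life tables and
# hazard models can be tested against known ground truth.

#' Siler (bathtub) mortality hazard
#'
#' \eqn{h(t) = a_1 e^{-b_1 t} + a_2 + a_3 e^{b_3 t}}: a declining infant
#' component, a constant adult component and an exponentially rising
#' senescent component.
#'
#' @param t age in years.
#' @param pars named vector with `a1`, `b1`, `a2`, `a3`, `b3` (hazards
#'   per year).
#' @return Hazard (per year) at each `t`.
#' @export
siler_hazard <- function(t, pars) {
  pars["a1"] * exp(-pars["b1"] * t) + pars["a2"] +
    pars["a3"] * exp(pars["b3"] * t)
}

#' Cumulative Siler hazard
#' @inheritParams siler_hazard
#' @return \eqn{H(t) = \int_0^t h(u)\,du}.
#' @export
siler_cumhaz <- function(t, pars) {
  inf_part <- if (pars["a1"] == 0) 0 else if (pars["b1"] > 0) {
    pars["a1"] / pars["b1"] * (1 - exp(-pars["b1"] * t))
  } else pars["a1"] * t
  sen_part <- if (pars["a3"] == 0) 0 else if (pars["b3"] > 0) {
    pars["a3"] / pars["b3"] * (exp(pars["b3"] * t) - 1)
  } else pars["a3"] * t
  unname(inf_part + pars["a2"] * t + sen_part)
}

# one death age from the Siler hazard, conditional on survival to `entry`
.rsiler1 <- function(pars, entry = 0) {
  target <- siler_cumhaz(entry, pars) + stats::rexp(1)
  upper <- entry + 1
  while (siler_cumhaz(upper, pars) < target && upper < entry + 500) {
    upper <- upper * 2 + 1
  }
  if (siler_cumhaz(upper, pars) < target) return(Inf)
  stats::uniroot(function(t) siler_cumhaz(t, pars) - target,
                 lower = entry, upper = upper, tol = 1e-9)$root
}

#' Simulation parameter set
#'
#' Defaults describe a generic cercopithecine population; use
#' [sim_preset()] for the calibrated `"chacma-like"` and `"gelada-like"`
#' parameter sets.
#'
#' @param n_units number of social units.
#' @param females_per_unit integer range (length 2) of founding females
#'   per unit at study onset.
#' @param study_years study duration (years).
#' @param mortality named Siler parameters `a1`, `b1` (infant decline),
#'   `a2` (constant adult), `a3`, `b3` (senescent rise), hazards/year.
#' @param maturation_age earliest conception age (years).
#' @param conception log-hazard coefficients (intercept, age, age2) of
#'   the conception process on standardized age.
#' @param age_center,age_scale standardization used by the conception
#'   hazard.
#' @param gestation gestation length (years).
#' @param postpartum_anoestrus years after a birth before the mother can
#'   conceive again; waived the moment the infant dies (infant death
#'   hastens the next birth).
#' @param takeover_rate per-unit male takeovers per year (Poisson).
#' @param weaning_age age (years) below which an infant is vulnerable to
#'   takeover infanticide.
#' @param p_infanticide probability a dependent infant is killed by a
#'   given takeover (death placed within the 180-day window).
#' @param p_orphan_death probability an infant under one year dies after
#'   its mother's death (within the 90-day window).
#' @param p_attack_observed probability the male attack behind an
#'   infanticide is observed or inferred (evidence channel used by
#'   chacma-style attribution).
#' @param p_illness_observed probability an intrinsic infant death is
#'   preceded by an observed injury/illness sign.
#' @param entry_staggering fraction of founding females entering the
#'   study mid-life (left truncation); the rest start as juveniles.
#' @param max_founder_age oldest mid-life entry age.
#' @param population population label written to the records.
#' @param seed default RNG seed for [simulate_population()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_units = 10, females_per_unit = c(3, 8),
                       study_years = 20,
                       mortality = c(a1 = 0.3, b1 = 2, a2 = 0.02,
                                     a3 = 0.002, b3 = 0.2),
                       maturation_age = 5.5,
                       conception = c(intercept = 0, age = 0.3,
                                      age2 = -0.4),
                       age_center = 12, age_scale = 6,
                       gestation = 0.5, postpartum_anoestrus = 0.6,
                       takeover_rate = 0.2, weaning_age = 1.5,
                       p_infanticide = 0.3, p_orphan_death = 0.7,
                       p_attack_observed = 0.9, p_illness_observed = 0.5,
                       entry_staggering = 0.6, max_founder_age = 16,
                       population = "simulated", seed = 1) {
  p <- as.list(environment())
  stopifnot(all(c("a1", "b1", "a2", "a3", "b3") %in% names(p$mortality)),
            p$gestation > 0, p$postpartum_anoestrus >= 0,
            all(unlist(p[c("p_infanticide", "p_orphan_death",
                           "p_attack_observed", "p_illness_observed",
                           "entry_staggering")]) >= 0),
            all(unlist(p[c("p_infanticide", "p_orphan_death",
                           "p_attack_observed", "p_illness_observed",
                           "entry_staggering")]) <= 1))
  class(p) <- "sim_params"
  p
}

#' Calibrated simulation presets
#'
#' `"chacma-like"`: one large multi-male group, frequent takeovers, high
#' infant mortality (first-year mortality near 35%), structural
#' interbirth floor near 1 year and mean closed intervals near 2 years.
#' `"gelada-like"`: many small one-male units, rarer takeovers, low
#' infant mortality (near 13%), earlier maturation and longer intervals
#' (mean near 2.6 years).
#'
#' @param name `"chacma-like"` or `"gelada-like"`.
#' @param ... overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_preset <- function(name = c("chacma-like", "gelada-like"), ...) {
  name <- match.arg(name)
  base <- if (name == "chacma-like") {
    list(n_units = 2, females_per_unit = c(9, 14), study_years = 15,
         mortality = c(a1 = 0.26, b1 = 2.2, a2 = 0.03, a3 = 0.0025,
                       b3 = 0.22),
         maturation_age = 6.0,
         conception = c(intercept = -0.22, age = 0.25, age2 = -0.45),
         age_center = 12, age_scale = 5,
         gestation = 0.5, postpartum_anoestrus = 0.45,
         takeover_rate = 0.45, weaning_age = 1.5,
         p_infanticide = 0.62, p_orphan_death = 0.75,
         p_attack_observed = 0.9, p_illness_observed = 0.4,
         entry_staggering = 0.7, max_founder_age = 16,
         population = "chacma")
  } else {
    list(n_units = 25, females_per_unit = c(2, 7), study_years = 16,
         mortality = c(a1 = 0.11, b1 = 2.2, a2 = 0.02, a3 = 0.0022,
                       b3 = 0.22),
         maturation_age = 5.5,
         conception = c(intercept = -0.70, age = 0.25, age2 = -0.4),
         age_center = 12, age_scale = 5,
         gestation = 0.5, postpartum_anoestrus = 0.55,
         takeover_rate = 0.18, weaning_age = 1.5,
         p_infanticide = 0.32, p_orphan_death = 0.75,
         p_attack_observed = 0.2, p_illness_observed = 0.4,
         entry_staggering = 0.7, max_founder_age = 16,
         population = "gelada")
  }
  do.call(sim_params, utils::modifyList(base, list(...)))
}

.conception_hazard <- function(age, p) {
  z <- (age - p$age_center) / p$age_scale
  exp(p$conception[1] + p$conception[2] * z + p$conception[3] * z^2)
}

#' Simulate a population of female life histories
#'
#' Discrete-event simulation in continuous time, recorded to day
#' resolution. Founding females enter at study onset (a fraction
#' mid-life, the rest juvenile); daughters born during the study enter
#' at birth, mature and reproduce in turn. All events are clipped to the
#' study window, giving left truncation and right censoring in the
#' output records. Deterministic given `seed`.
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param start_date calendar date of study onset.
#' @return List with `records` (a `demog_records` collection), `truth`
#'   (one row per infant: true cause of death among
#'   `maternal_death` / `infanticide` / `intrinsic` / `none`, true death
#'   age), and `params`.
#' @export
simulate_population <- function(params, seed = params$seed,
                                start_date = as.Date("2000-01-01")) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  Y <- params$study_years
  adult_grid <- seq(params$maturation_age, 60, by = 0.1)
  lam_max <- max(.conception_hazard(adult_grid, params)) * 1.0001

  l5 <- exp(-siler_cumhaz(5, params$mortality))
  if (l5 < 1e-4) {
    stop("mortality parameters give essentially zero adult survivorship",
         call. = FALSE)
  }

  # takeover times per unit
  units <- sprintf("U%02d", seq_len(params$n_units))
  takeover_times <- lapply(units, function(u) {
    n <- stats::rpois(1, params$takeover_rate * Y)
    sort(stats::runif(n, 0, Y))
  })
  names(takeover_times) <- units

  females <- list()   # rows of the females table (study-time units)
  births <- list()
  fates <- list()
  truth <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("ID%05d", counter)
  }

  # queue of females to process: list(id, unit, birth (study time, may be
  # negative for founders), death (study time), founder, known)
  queue <- list()
  for (u in units) {
    n_f <- sample(params$females_per_unit[1]:params$females_per_unit[2], 1)
    for (i in seq_len(n_f)) {
      midlife <- stats::runif(1) < params$entry_staggering
      age0 <- if (midlife) {
        stats::runif(1, params$maturation_age, params$max_founder_age)
      } else stats::runif(1, 0, params$maturation_age)
      death <- .rsiler1(params$mortality, entry = age0) - age0
      queue[[length(queue) + 1L]] <- list(
        id = new_id(), unit = u, birth = -age0, death = death,
        founder = TRUE, known = !midlife)
    }
  }

  simulate_infant <- function(tb, mother_death, unit) {
    # competing channels; all times are study-time
    nat <- tb + .rsiler1(params$mortality)
    cands <- c(intrinsic = nat)
    if (mother_death > tb && (mother_death - tb) < 1 &&
        stats::runif(1) < params$p_orphan_death) {
      cands["maternal_death"] <- mother_death +
        stats::runif(1, 0, 88) / DAYS_PER_YEAR
    }
    tos <- takeover_times[[unit]]
    tos <- tos[tos >= tb & tos < tb + params$weaning_age]
    for (to in tos) {
      if (stats::runif(1) < params$p_infanticide) {
        cands["infanticide"] <- to + stats::runif(1, 0, 178) / DAYS_PER_YEAR
        break
      }
    }
    k <- which.min(cands)
    list(death = cands[[k]], cause = names(cands)[k])
  }

  qi <- 1L
  while (qi <= length(queue)) {
    f <- queue[[qi]]; qi <- qi + 1L
    # record the female if observed during the study
    entry <- max(f$birth, 0)
    depart <- min(f$death, Y)
    if (depart >= entry) {
      females[[length(females) + 1L]] <- data.frame(
        female_id = f$id, population = params$population,
        birth_time = f$birth, birth_date_known = f$known,
        entry_time = entry, depart_time = depart,
        depart_type = if (f$death <= Y) "death" else "censored",
        unit_id = f$unit, stringsAsFactors = FALSE)
    }

    # reproduction
    t_clock <- max(f$birth + params$maturation_age, 0)
    end <- min(f$death, Y)
    while (t_clock < end) {
      # thinned Poisson conception proposal
      t_prop <- t_clock
      conceived <- NA_real_
      repeat {
        t_prop <- t_prop + stats::rexp(1, lam_max)
        if (t_prop >= end) break
        age <- t_prop - f$birth
        if (stats::runif(1) < .conception_hazard(age, params) / lam_max) {
          conceived <- t_prop
          break
        }
      }
      if (is.na(conceived)) break
      tb <- conceived + params$gestation
      if (tb >= f$death) break        # died pregnant
      if (tb > Y) break               # birth unobserved
      iid <- new_id()
      inf <- simulate_infant(tb, f$death, f$unit)
      births[[length(births) + 1L]] <- data.frame(
        infant_id = iid, mother_id = f$id, birth_time = tb,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        infant_id = iid, mother_id = f$id, birth_time = tb,
        true_death_age = inf$death - tb,
        true_cause = if (inf$death - tb <= 1) inf$cause else "none",
        stringsAsFactors = FALSE)

      # fate row
      died_in_study <- inf$death <= Y
      attack_seen <- inf$cause == "infanticide" &&
        stats::runif(1) < params$p_attack_observed
      ill_seen <- inf$cause == "intrinsic" &&
        stats::runif(1) < params$p_illness_observed
      ill_date <- if (ill_seen && died_in_study) {
        max(inf$death - stats::runif(1, 0, 28) / DAYS_PER_YEAR, tb)
      } else NA_real_
      mdis <- if (f$death <= Y && f$death <= min(inf$death, Y)) {
        f$death
      } else NA_real_
      fates[[length(fates) + 1L]] <- data.frame(
        infant_id = iid,
        death_time = if (died_in_study) inf$death else NA_real_,
        censor_time = if (died_in_study) NA_real_ else Y,
        observed_attack = died_in_study && attack_seen,
        illness_or_injury_observed = died_in_study && ill_seen,
        illness_observation_time = if (died_in_study) ill_date else NA_real_,
        mother_disappearance_time = mdis, stringsAsFactors = FALSE)

      # daughter becomes a tracked female
      if (stats::runif(1) < 0.5) {
        queue[[length(queue) + 1L]] <- list(
          id = iid, unit = f$unit, birth = tb, death = inf$death,
          founder = FALSE, known = TRUE)
      }
      anoestrus_end <- tb + params$postpartum_anoestrus
      t_clock <- min(anoestrus_end, inf$death)
    }
  }

  to_date <- function(t) start_date + round(t * DAYS_PER_YEAR)
  fem <- do.call(rbind, females)
  fem_df <- data.frame(female_id = fem$female_id,
                       population = fem$population,
                       birth_date = to_date(fem$birth_time),
                       birth_date_known = fem$birth_date_known,
                       entry_date = to_date(fem$entry_time),
                       depart_date = to_date(fem$depart_time),
                       depart_type = fem$depart_type,
                       unit_id = fem$unit_id, stringsAsFactors = FALSE)
  b <- do.call(rbind, births)
  births_df <- if (is.null(b)) data.frame(
    infant_id = character(0), mother_id = character(0),
    birth_date = as.Date(character(0)), date_accuracy_days = numeric(0)) else
    data.frame(infant_id = b$infant_id, mother_id = b$mother_id,
               birth_date = to_date(b$birth_time), date_accuracy_days = 0,
               stringsAsFactors = FALSE)
  ft <- do.call(rbind, fates)
  fates_df <- if (is.null(ft)) data.frame(
    infant_id = character(0), death_date = as.Date(character(0)),
    censor_date = as.Date(character(0)), observed_attack = logical(0),
    illness_or_injury_observed = logical(0),
    illness_observation_date = as.Date(character(0)),
    mother_disappearance_date = as.Date(character(0))) else
    data.frame(infant_id = ft$infant_id,
               death_date = to_date(ft$death_time),
               censor_date = to_date(ft$censor_time),
               observed_attack = ft$observed_attack,
               illness_or_injury_observed = ft$illness_or_injury_observed,
               illness_observation_date = to_date(ft$illness_observation_time),
               mother_disappearance_date = to_date(ft$mother_disappearance_time),
               stringsAsFactors = FALSE)
  takeovers_df <- data.frame(
    unit_id = rep(units, lengths(takeover_times)),
    takeover_date = to_date(unlist(takeover_times)),
    stringsAsFactors = FALSE)

  truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
    infant_id = character(0), mother_id = character(0),
    birth_time = numeric(0), true_death_age = numeric(0),
    true_cause = character(0))

  recs <- demog_records(fem_df, births_df, fates_df, takeovers_df)
  list(records = recs, truth = truth_df, params = params)
}
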