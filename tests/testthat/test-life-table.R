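test_that("no deaths means flat survivorship", {
  f <- rbind(make_female("A", "2000-01-01", depart = "2003-01-01"),
             make_female("B", "2000-01-01", depart = "2003-01-01"))
  lt <- build_life_table(demog_records(f, empty_births(), empty_fates(),
                                       empty_takeovers()))
  expect_true(all(lt$l_x == 1))
  expect_true(all(lt$q_x[lt$n_risk_survival > 0] == 0))
})

test_that("three-female fixture reproduces the hand enumeration exactly", {
  lt <- build_life_table(make_fixture("lifetable-basic"))
  expect_identical(lt$n_risk_survival[1:4], c(2, 2, 2, 1))
  expect_identical(lt$n_deaths[1:3], c(0L, 1L, 0L))
  expect_identical(lt$q_x[1], 0)
  expect_identical(lt$q_x[2], 0.5)
  expect_identical(lt$l_x[3], 0.5)
  expect_identical(lt$l_x[4], 0.5)
})

test_that("per-class conservation: at risk = deaths + censored + continuing", {
  sim <- simulate_population(sim_preset("gelada-like"), seed = 4)
  recs <- sim$records
  lt <- build_life_table(recs)
  f <- recs$females
  entry_age <- as.numeric(f$entry_date - f$birth_date) / 365.25
  depart_age <- as.numeric(f$depart_date - f$birth_date) / 365.25
  death <- f$depart_type == "death"
  for (x in lt$x) {
    at_risk <- lt$n_risk_survival[lt$x == x]
    classes <- mapply(function(e, dd, dth)
      list(senodemog:::.risk_classes(e, dd, dth)),
      entry_age, depart_age, death)
    in_x <- vapply(classes, function(cl) x %in% cl, logical(1))
    cont <- vapply(classes, function(cl) (x + 1) %in% cl, logical(1))
    deaths_x <- sum(death & floor(depart_age) == x)
    censored_x <- sum(in_x & !cont & !(death & floor(depart_age) == x))
    expect_equal(at_risk, deaths_x + censored_x + sum(in_x & cont))
  }
})

test_that("without truncation or censoring l_x is the cohort survival fraction", {
  set.seed(2)
  n <- 40
  death_age <- rexp(n, 0.25) + 0.1
  f <- do.call(rbind, lapply(seq_len(n), function(i)
    make_female(paste0("F", i), "2000-01-01",
                depart = as.character(d_("2000-01-01") +
                                        round(death_age[i] * 365.25)),
                type = "death")))
  lt <- build_life_table(demog_records(f, empty_births(), empty_fates(),
                                       empty_takeovers()))
  age_obs <- as.numeric(f$depart_date - f$birth_date) / 365.25
  for (x in lt$x) {
    expect_equal(lt$l_x[lt$x == x], mean(age_obs >= x))
  }
})

test_that("constant adult hazard gives q_x near 1 - exp(-mu)", {
  mu <- 0.05
  p <- sim_preset("gelada-like",
                  mortality = c(a1 = 0, b1 = 1, a2 = mu, a3 = 0, b3 = 1),
                  takeover_rate = 0, p_orphan_death = 0,
                  n_units = 40, study_years = 20)
  sim <- simulate_population(p, seed = 6)
  lt <- build_life_table(sim$records)
  adult <- lt$x >= 6 & lt$x <= 14 & lt$n_risk_survival >= 30
  q_hat <- sum(lt$n_deaths[adult]) / sum(lt$n_risk_survival[adult])
  n_tot <- sum(lt$n_risk_survival[adult])
  q_true <- 1 - exp(-mu)
  expect_lt(abs(q_hat - q_true), 3 * sqrt(q_true * (1 - q_true) / n_tot))
})

test_that("expected lifetime reproduction matches closed forms", {
  lt <- toy_life_table(l = rep(1, 5), m = c(0, 1, 1, 1, 0))
  expect_equal(expected_lifetime_reproduction(lt, 0), 3.0)
  expect_equal(expected_lifetime_reproduction(lt, 1), 3.0)
  lt2 <- make_fixture("prr-toy")
  # by hand: sum l_x m_x = 0.5 + 0.5 = 1
  expect_equal(expected_lifetime_reproduction(lt2, 0), 1.0)
  # conditioning on a zero-survivorship class errors
  expect_error(expected_lifetime_reproduction(lt2, 5), "zero")
})

test_that("lifetime reproduction at birth matches mean simulated births", {
  p <- sim_preset("gelada-like", n_units = 150, study_years = 45,
                  entry_staggering = 0, takeover_rate = 0,
                  p_orphan_death = 0)
  sim <- simulate_population(p, seed = 13)
  lt <- build_life_table(sim$records)
  e0 <- expected_lifetime_reproduction(lt, 0)
  # cohort oracle: mean lifetime births of females born early enough in
  # the study that their whole lifespan was observed (died in-study)
  f <- sim$records$females
  start <- min(f$entry_date)
  early <- f$birth_date >= start & f$birth_date <= start + round(8 * 365.25)
  complete <- early & f$depart_type == "death"
  ids <- f$female_id[complete]
  births_per <- table(factor(sim$records$births$mother_id, levels = ids))
  expect_gt(length(ids), 200)
  expect_equal(e0, mean(births_per), tolerance = 0.3)
})

test_that("age-class binomial regression recovers shape and nulls", {
  # identical proportions across ages: age terms vanish
  lt_flat <- toy_life_table(l = cumprod(c(1, rep(0.9, 9))),
                            m = rep(0.3, 10), n_risk = 500)
  lt_flat$n_births <- round(lt_flat$n_risk_fertility * 0.3)
  lt_flat$n_deaths <- round(lt_flat$n_risk_survival * 0.1)
  g0 <- fit_ageclass_glm(list(a = lt_flat), "births")
  expect_lt(abs(g0$coefficients["age"]), 3 * g0$se["age"])
  expect_lt(abs(g0$coefficients["age2"]), 3 * g0$se["age2"])

  # known quadratic logit curve, 500 per class
  set.seed(14)
  x <- 0:19
  z <- (x - mean(x)) / sd(x)
  p_true <- plogis(-0.5 + 0.6 * z - 1.1 * z^2)
  lt_q <- toy_life_table(l = rep(1, 20), m = p_true, n_risk = 500)
  lt_q$n_births <- rbinom(20, 500, p_true)
  lt_q$n_deaths <- 0L
  g1 <- fit_ageclass_glm(list(a = lt_q), "births")
  expect_lt(abs(g1$coefficients["age"] - 0.6), 2 * g1$se["age"])
  expect_lt(abs(g1$coefficients["age2"] + 1.1), 2 * g1$se["age2"])

  # simulated population fertility is inverted-U: negative age^2 term
  sim <- simulate_population(sim_preset("gelada-like"), seed = 2)
  lt <- build_life_table(sim$records)
  g2 <- fit_ageclass_glm(list(gelada = lt), "births")
  expect_lt(g2$coefficients["age2"], 0)
  expect_gt(abs(g2$coefficients["age2"]), 2 * g2$se["age2"])
})
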