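# interval extraction, infant dataset and cause attribution rules

base_mother <- function(depart = "2010-01-01", type = "censored") {
  make_female("M1", "1995-01-01", entry = "2000-01-01", depart = depart,
              type = type)
}

test_that("interval extraction: closed, excluded and censored cases", {
  # two births 2.0 yr apart (730.5 days -> use 731), first infant survives
  f <- base_mother()
  b <- rbind(make_birth("I1", "M1", "2001-01-01"),
             make_birth("I2", "M1", d_("2001-01-01") + 731))
  ft <- rbind(make_fate("I1", censor = "2010-01-01"),
              make_fate("I2", censor = "2010-01-01"))
  iv <- extract_intervals(demog_records(f, b, ft, empty_takeovers()))
  expect_identical(nrow(iv), 2L)             # closed + trailing censored
  expect_true(iv$closed[1])
  expect_equal(iv$duration[1], 731 / 365.25, tolerance = 1e-12)
  expect_equal(iv$maternal_age_at_start[1],
               age_at(list(birth_date = d_("1995-01-01")), d_("2001-01-01")))

  # first infant dies at 0.3 yr before next birth at 1.2 yr: excluded
  ft2 <- rbind(make_fate("I1", death = d_("2001-01-01") + 110),
               make_fate("I2", censor = "2010-01-01"))
  b2 <- rbind(make_birth("I1", "M1", "2001-01-01"),
              make_birth("I2", "M1", d_("2001-01-01") + 438))
  iv2 <- extract_intervals(demog_records(f, b2, ft2, empty_takeovers()))
  expect_false(any(iv2$closed))

  # single birth, mother censored 1.6 yr later, infant survives
  f3 <- base_mother(depart = as.character(d_("2001-01-01") + 584))
  b3 <- make_birth("I1", "M1", "2001-01-01")
  ft3 <- make_fate("I1", censor = as.character(d_("2001-01-01") + 584))
  iv3 <- extract_intervals(demog_records(f3, b3, ft3, empty_takeovers()),
                           drop_short_censored = FALSE)
  expect_identical(nrow(iv3), 1L)
  expect_false(iv3$closed)
  expect_equal(iv3$duration, 584 / 365.25, tolerance = 1e-12)
})

test_that("entry offset equals the population's minimum closed interval", {
  sim <- simulate_population(sim_preset("chacma-like"), seed = 3)
  iv <- extract_intervals(sim$records, "chacma")
  expect_equal(unique(iv$entry_offset), min(iv$duration[iv$closed]))
  expect_true(all(iv$duration >= iv$entry_offset))
  # the chacma-like regime has its structural floor near one year
  expect_gt(iv$entry_offset[1], 0.9)
  expect_lt(iv$entry_offset[1], 1.2)
})

test_that("closed intervals are unaffected by fate edits of the closing infant", {
  sim <- simulate_population(sim_preset("gelada-like", n_units = 6),
                             seed = 11)
  iv0 <- extract_intervals(sim$records)
  closed0 <- iv0[iv0$closed, c("mother_id", "start_birth_date", "duration")]
  # kill every infant that OPENS no interval (i.e. is a closing birth):
  # mark all second-and-later infants as dying late; closed intervals are
  # keyed on the opening infant's survival only
  edited <- sim$records
  openers <- unique(format(closed0$start_birth_date))
  idx <- match(edited$fates$infant_id, edited$births$infant_id)
  is_opener <- format(edited$births$birth_date[idx]) %in% openers
  flip <- which(!is_opener & is.na(edited$fates$death_date))[1:5]
  flip <- flip[!is.na(flip)]
  edited$fates$death_date[flip] <- edited$births$birth_date[idx[flip]] + 3000
  edited$fates$censor_date[flip] <- NA
  iv1 <- extract_intervals(edited)
  closed1 <- iv1[iv1$closed, c("mother_id", "start_birth_date", "duration")]
  expect_equal(closed1, closed0, ignore_attr = TRUE)
})

test_that("cause attribution follows the documented precedence", {
  takeovers <- empty_takeovers()
  # death 80 days after mother's disappearance
  fate <- make_fate("I1", death = "2003-03-22", mdis = "2003-01-01")
  expect_identical(attribute_cause(fate, takeovers, "chacma")$category,
                   "maternal_death")
  # gelada death 100 days after a unit takeover, mother alive
  to <- data.frame(unit_id = "U1", takeover_date = d_("2003-01-01"))
  fate2 <- make_fate("I1", death = d_("2003-01-01") + 100)
  res2 <- attribute_cause(fate2, to, "gelada", unit_id = "U1")
  expect_identical(res2$category, "infanticide")
  expect_identical(res2$evidence, "takeover_window")
  # no evidence at all
  fate3 <- make_fate("I1", death = "2003-06-01")
  expect_identical(attribute_cause(fate3, takeovers, "gelada",
                                   unit_id = "U1")$category, "unknown")
  # both windows fire: maternal death wins
  cc <- make_fixture("cause-conflict")
  res4 <- attribute_cause(cc$fates[1, ], cc$takeovers, "gelada", "U1")
  expect_identical(res4$category, "maternal_death")
  # brute-force check that both windows indeed fire for that fixture
  lag_m <- as.numeric(cc$fates$death_date[1] -
                        cc$fates$mother_disappearance_date[1])
  lag_t <- as.numeric(cc$fates$death_date[1] - cc$takeovers$takeover_date[1])
  expect_true(lag_m >= 0 && lag_m <= 90)
  expect_true(lag_t >= 0 && lag_t <= 180)
  # outside the windows the same evidence does not fire
  fate5 <- make_fate("I1", death = "2003-06-01", mdis = "2003-01-01")
  expect_identical(attribute_cause(fate5, takeovers, "chacma")$category,
                   "unknown")
  # chacma infanticide needs an observed/inferred attack, not takeovers
  fate6 <- make_fate("I1", death = d_("2003-01-01") + 100, attack = TRUE)
  expect_identical(attribute_cause(fate6, to, "chacma")$category,
                   "infanticide")
  # illness window is 30 days
  fate7 <- make_fate("I1", death = "2003-06-01", ill = TRUE,
                     ill_date = "2003-05-20")
  expect_identical(attribute_cause(fate7, takeovers, "chacma")$category,
                   "injury_or_illness")
  fate8 <- make_fate("I1", death = "2003-06-01", ill = TRUE,
                     ill_date = "2003-04-01")
  expect_identical(attribute_cause(fate8, takeovers, "chacma")$category,
                   "unknown")
})

test_that("infant dataset: observation window, causes and hand enumeration", {
  f <- base_mother()
  births <- do.call(rbind, lapply(1:4, function(i)
    make_birth(paste0("I", i), "M1",
               as.character(d_("2001-01-01") + (i - 1) * 800))))
  fates <- rbind(
    make_fate("I1", death = d_("2001-01-01") + 146),        # dies at 0.4 yr
    make_fate("I2", censor = "2010-01-01"),                 # survives
    make_fate("I3", censor = d_("2001-01-01") + 1600 + 100),# censored at 0.27
    make_fate("I4", death = d_("2001-01-01") + 2400 + 500)) # dies after 1 yr
  inf <- build_infant_dataset(demog_records(f, births, fates,
                                            empty_takeovers()))
  expect_identical(nrow(inf), 4L)
  expect_equal(inf$time_observed[1], 146 / 365.25, tolerance = 1e-12)
  expect_true(inf$died[1])
  expect_identical(inf$cause[1], "unknown")
  expect_equal(inf$time_observed[2], 1.0)
  expect_false(inf$died[2])
  expect_true(is.na(inf$cause[2]))
  expect_identical(inf$cause[3], "censored")
  expect_false(inf$died[4])            # death after age one
  expect_equal(inf$time_observed[4], 1.0)
})

test_that("every fate-known death receives exactly one cause", {
  sim <- simulate_population(sim_preset("chacma-like"), seed = 8)
  inf <- build_infant_dataset(sim$records, missing_fates = "censor")
  deaths <- inf[inf$died, ]
  expect_true(all(deaths$cause %in% c("maternal_death", "infanticide",
                                      "injury_or_illness", "unknown")))
  expect_identical(sum(table(deaths$cause)), nrow(deaths))
})
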