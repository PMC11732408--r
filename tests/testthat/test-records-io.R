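test_that("round-trip through CSV is the identity on all fields", {
  sim <- simulate_population(sim_preset("gelada-like",
                                        n_units = 4, study_years = 8),
                             seed = 5)
  dir <- withr::local_tempdir()
  write_records(sim$records, dir, force = TRUE)
  back <- read_records(dir)
  for (tab in c("females", "births", "fates", "takeovers")) {
    a <- sim$records[[tab]]; b <- back[[tab]]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, ignore_attr = TRUE)
  }
})

test_that("empty births file with a valid header is accepted", {
  dir <- withr::local_tempdir()
  recs <- demog_records(make_female("A", "2000-01-01", depart = "2004-01-01"),
                        empty_births(), empty_fates(), empty_takeovers())
  write_records(recs, dir, force = TRUE)
  back <- read_records(dir)
  expect_identical(nrow(back$births), 0L)
})

test_that("validation rejects invariant violations with informative errors", {
  f <- make_female("A", "2000-01-01", depart = "2005-01-01")
  b <- make_birth("I1", "A", "2004-06-01")
  # death and censor both set
  ft_bad <- make_fate("I1", death = "2004-09-01", censor = "2004-10-01")
  expect_error(demog_records(f, b, ft_bad, empty_takeovers()),
               "both death_date and censor_date")
  # dangling mother id
  b_bad <- make_birth("I1", "ZZ", "2004-06-01")
  expect_error(demog_records(f, b_bad, make_fate("I1", censor = "2005-01-01"),
                             empty_takeovers()),
               "mother_id not found")
  # entry before birth
  f_bad <- make_female("A", "2000-01-01", entry = "1999-01-01",
                       depart = "2005-01-01")
  expect_error(demog_records(f_bad, empty_births(), empty_fates(),
                             empty_takeovers()),
               "entry_date before birth_date")
  # birth before maturation
  b_early <- make_birth("I1", "A", "2001-01-01")
  expect_error(demog_records(f, b_early, make_fate("I1", censor = "2005-01-01"),
                             empty_takeovers()),
               "maturation")
})

test_that("randomized single-field corruptions are all rejected", {
  sim <- simulate_population(sim_preset("chacma-like", study_years = 6),
                             seed = 9)
  recs <- sim$records
  set.seed(42)
  for (k in 1:20) {
    bad <- recs
    kind <- sample(4, 1)
    if (kind == 1 && nrow(bad$females)) {
      i <- sample(nrow(bad$females), 1)
      bad$females$entry_date[i] <- bad$females$birth_date[i] - 10
    } else if (kind == 2 && nrow(bad$females)) {
      i <- sample(nrow(bad$females), 1)
      bad$females$depart_type[i] <- "vanished"
    } else if (kind == 3 && nrow(bad$births)) {
      i <- sample(nrow(bad$births), 1)
      bad$births$mother_id[i] <- "NOSUCH"
    } else if (nrow(bad$fates)) {
      i <- sample(nrow(bad$fates), 1)
      bad$fates$death_date[i] <- NA
      bad$fates$censor_date[i] <- NA
    }
    expect_error(validate_records(bad))
  }
})

test_that("unparseable dates are reported with their line number", {
  dir <- withr::local_tempdir()
  recs <- demog_records(make_female("A", "2000-01-01", depart = "2004-01-01"),
                        empty_births(), empty_fates(), empty_takeovers())
  write_records(recs, dir, force = TRUE)
  females <- readLines(file.path(dir, "females.csv"))
  females[2] <- sub("2000-01-01", "01/02/2000", females[2])
  writeLines(females, file.path(dir, "females.csv"))
  expect_error(read_records(dir), "unparseable date.*line")
})

test_that("missing columns name the file and column", {
  dir <- withr::local_tempdir()
  recs <- demog_records(make_female("A", "2000-01-01", depart = "2004-01-01"),
                        empty_births(), empty_fates(), empty_takeovers())
  write_records(recs, dir, force = TRUE)
  f <- utils::read.csv(file.path(dir, "females.csv"))
  f$depart_type <- NULL
  utils::write.csv(f, file.path(dir, "females.csv"), row.names = FALSE)
  expect_error(read_records(dir), "females.csv.*depart_type")
})

test_that("age_at uses a fixed 365.25-day year", {
  fem <- list(birth_date = as.Date("2000-01-01"))
  expect_identical(age_at(fem, as.Date("2000-01-01")), 0)
  expect_equal(age_at(fem, as.Date("2000-01-01") + 731), 2.0, tolerance = 2e-3)
  # day-count oracle: 2000-01-01 .. 2006-07-02 spans 2374 days
  expect_equal(age_at(fem, as.Date("2006-07-02")), 2374 / 365.25,
               tolerance = 1e-12)
  expect_equal(age_at(fem, as.Date("2006-07-02")), 6.5, tolerance = 0.01)
  expect_error(age_at(fem, as.Date("1999-12-31")), "precedes")
})
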