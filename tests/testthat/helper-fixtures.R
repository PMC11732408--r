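# shared helpers: small record collections and simulated datasets built
# in code at test time

d_ <- function(x) as.Date(x)

empty_births <- function() {
  data.frame(infant_id = character(0), mother_id = character(0),
             birth_date = d_(character(0)), date_accuracy_days = numeric(0))
}
empty_fates <- function() {
  data.frame(infant_id = character(0), death_date = d_(character(0)),
             censor_date = d_(character(0)), observed_attack = logical(0),
             illness_or_injury_observed = logical(0),
             illness_observation_date = d_(character(0)),
             mother_disappearance_date = d_(character(0)))
}
empty_takeovers <- function() {
  data.frame(unit_id = character(0), takeover_date = d_(character(0)))
}

make_female <- function(id, birth, entry = birth, depart,
                        type = "censored", pop = "chacma", unit = "U1",
                        known = TRUE) {
  data.frame(female_id = id, population = pop, birth_date = d_(birth),
             birth_date_known = known, entry_date = d_(entry),
             depart_date = d_(depart), depart_type = type,
             unit_id = unit, stringsAsFactors = FALSE)
}

make_birth <- function(iid, mid, date, acc = 0) {
  data.frame(infant_id = iid, mother_id = mid, birth_date = d_(date),
             date_accuracy_days = acc, stringsAsFactors = FALSE)
}

make_fate <- function(iid, death = NA, censor = NA, attack = FALSE,
                      ill = FALSE, ill_date = NA, mdis = NA) {
  data.frame(infant_id = iid, death_date = d_(death),
             censor_date = d_(censor), observed_attack = attack,
             illness_or_injury_observed = ill,
             illness_observation_date = d_(ill_date),
             mother_disappearance_date = d_(mdis),
             stringsAsFactors = FALSE)
}

# life table that satisfies the parallel-decline null exactly: after the
# fertility peak, m declines in proportion to survivorship
null_life_table <- function() {
  K <- 26
  q <- c(0.25, rep(0.04, 4), rep(0.06, 10), rep(0.18, K - 15))
  l <- cumprod(c(1, 1 - q))[1:K]
  m <- numeric(K)
  peak <- 9
  m[6:peak] <- seq(0.15, 0.42, length.out = 4)
  m[(peak + 1):K] <- 0.42 * l[(peak + 1):K] / l[peak]
  toy_life_table(l, m)
}

# cohort sampled from a life table's q/m schedules (no censoring);
# independent of the package's null machinery except .cohort_table
sample_cohort_table <- function(lt, n_females) {
  K <- nrow(lt)
  q <- ifelse(is.na(lt$q_x), 0, lt$q_x)
  m <- pmin(ifelse(is.na(lt$m_x), 0, lt$m_x), 1)
  l <- cumprod(c(1, 1 - q))
  dth <- l[1:K] - l[2:(K + 1)]
  death_class <- sample.int(K + 1, n_females, TRUE,
                            prob = c(dth, l[K + 1])) - 1L
  n_risk <- vapply(0:(K - 1), function(x) sum(death_class >= x), integer(1))
  n_deaths <- vapply(0:(K - 1), function(x) sum(death_class == x), integer(1))
  n_births <- stats::rbinom(K, n_risk, m)
  cohort_life_table(n_risk, n_deaths, n_births)
}

# infant_data frame from raw pieces (for the cause GLMs)
make_infants <- function(age, died, cause, years = 2000) {
  n <- length(age)
  out <- data.frame(infant_id = sprintf("I%04d", seq_len(n)),
                    mother_id = "M", maternal_age_at_birth = age,
                    time_observed = ifelse(died, 0.5, 1), died = died,
                    cause = cause,
                    birth_year = rep_len(years, n), unit_id = "U1",
                    population = "test", stringsAsFactors = FALSE)
  class(out) <- c("infant_data", "data.frame")
  out
}
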