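# Hand-sized deterministic fixtures with hand-computed expected outputs,
# used throughout the unit tests and runnable examples.

#' Build a toy life table from survivorship and fertility vectors
#'
#' @param l survivorship `l_x` over classes `0, 1, ...` (l beyond the
#'   table is taken as `l` of the last class times its survival).
#' @param m per-class birth probabilities `m_x`.
#' @param n_risk nominal at-risk count per class (bookkeeping only).
#' @return A `life_table` object with `q_x` implied by `l` and
#'   trapezoidal `L_x`.
#' @export
toy_life_table <- function(l, m, n_risk = 100) {
  stopifnot(length(l) == length(m), l[1] == 1, !is.unsorted(rev(l)))
  K <- length(l)
  l_next <- c(l[-1], 0)
  q <- ifelse(l > 0, 1 - l_next / l, NA_real_)
  L <- (l + l_next) / 2
  out <- data.frame(x = seq_len(K) - 1L, n_risk_survival = n_risk,
                    n_deaths = NA_integer_, q_x = q, l_x = l,
                    n_risk_fertility = n_risk, n_births = NA_integer_,
                    m_x = m, L_x = L)
  attr(out, "population") <- "toy"
  attr(out, "convention") <- "count"
  class(out) <- c("life_table", "data.frame")
  out
}

#' Deterministic test fixtures
#'
#' Tiny hand-constructed datasets with known expected outputs:
#' \describe{
#'   \item{`"lifetable-basic"`}{three females (one entering at birth and
#'     dying in class 1–2, one entering mid-life at age 2 and censored
#'     at 4.2, one entering at birth and censored at 3), giving
#'     `q_0 = 0`, `q_1 = 1/2`, `l_2 = l_3 = 0.5`. Returns a
#'     `demog_records` collection.}
#'   \item{`"prr-toy"`}{the toy life table `l = (1,1,1,1,0.5,0)`,
#'     `m = (0,0.5,0.5,0,0,0)` whose PrR is 1/3 under the package's
#'     boundary conventions. Returns a `life_table`.}
#'   \item{`"cause-conflict"`}{one gelada infant death falling both 80
#'     days after its mother's disappearance and 100 days after a unit
#'     takeover, exercising the maternal-death > infanticide precedence.
#'     Returns a `demog_records` collection.}
#' }
#'
#' @param name fixture name.
#' @return See above; unknown names are an error.
#' @export
make_fixture <- function(name = c("lifetable-basic", "prr-toy",
                                  "cause-conflict")) {
  name <- match.arg(name)
  d <- as.Date
  switch(name,
    "lifetable-basic" = {
      females <- data.frame(
        female_id = c("A", "B", "C"),
        population = "toy",
        birth_date = d(c("2000-01-01", "1997-12-31", "2000-01-01")),
        birth_date_known = c(TRUE, FALSE, TRUE),
        entry_date = d(c("2000-01-01", "2000-01-01", "2000-01-01")),
        # A dies at age 1.50; B censored at age ~4.2; C censored at ~3.0
        depart_date = d(c("2000-01-01", "1997-12-31", "2000-01-01")) +
          c(548, 1534, 1095),
        depart_type = c("death", "censored", "censored"),
        unit_id = "U1", stringsAsFactors = FALSE)
      empty_births <- data.frame(infant_id = character(0),
                                 mother_id = character(0),
                                 birth_date = d(character(0)),
                                 date_accuracy_days = numeric(0))
      empty_fates <- data.frame(infant_id = character(0),
                                death_date = d(character(0)),
                                censor_date = d(character(0)),
                                observed_attack = logical(0),
                                illness_or_injury_observed = logical(0),
                                illness_observation_date = d(character(0)),
                                mother_disappearance_date = d(character(0)))
      empty_takeovers <- data.frame(unit_id = character(0),
                                    takeover_date = d(character(0)))
      demog_records(females, empty_births, empty_fates, empty_takeovers)
    },
    "prr-toy" = toy_life_table(l = c(1, 1, 1, 1, 0.5, 0),
                               m = c(0, 0.5, 0.5, 0, 0, 0)),
    "cause-conflict" = {
      females <- data.frame(
        female_id = "M1", population = "gelada",
        birth_date = d("1995-01-01"), birth_date_known = TRUE,
        entry_date = d("2000-01-01"),
        depart_date = d("2003-06-01"),   # mother's disappearance (death)
        depart_type = "death", unit_id = "U1", stringsAsFactors = FALSE)
      births <- data.frame(infant_id = "I1", mother_id = "M1",
                           birth_date = d("2003-01-01"),
                           date_accuracy_days = 0,
                           stringsAsFactors = FALSE)
      # death 80 days after the disappearance AND 100 days after a takeover
      fates <- data.frame(infant_id = "I1",
                          death_date = d("2003-06-01") + 80,
                          censor_date = d(NA),
                          observed_attack = FALSE,
                          illness_or_injury_observed = FALSE,
                          illness_observation_date = d(NA),
                          mother_disappearance_date = d("2003-06-01"),
                          stringsAsFactors = FALSE)
      takeovers <- data.frame(unit_id = "U1",
                              takeover_date = d("2003-06-01") + 80 - 100,
                              stringsAsFactors = FALSE)
      demog_records(females, births, fates, takeovers)
    })
}
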