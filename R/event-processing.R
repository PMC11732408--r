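# Rule-based derivation of analysis datasets from raw demographic records:
# interbirth intervals (with right censoring and delayed entry), the
# infant-survival dataset to age one, and cause-of-death attribution.

#' Extract interbirth intervals for one population
#'
#' One record per consecutive birth pair (closed interval) or per final
#' birth (right-censored at the mother's departure). Intervals whose
#' opening infant died before the interval resolved are excluded, because
#' infant death hastens the next birth and would contaminate estimates of
#' the intrinsic pace of reproduction: for closed intervals the opening
#' infant must survive to the subsequent birth; for censored intervals it
#' must survive its first year.
#'
#' Mothers enter each interval only once they reach the population's
#' minimum observed closed-interval duration (`entry_offset`), giving a
#' delayed-entry risk set for the survival models.
#'
#' @param recs a `demog_records` collection.
#' @param population population label to subset on (default: all).
#' @param drop_short_censored drop censored intervals shorter than the
#'   entry offset (they contribute no risk time under delayed entry).
#' @return A data frame of class `ibi_data` with columns `mother_id`,
#'   `start_birth_date`, `maternal_age_at_start` (years),
#'   `duration` (years), `closed`, `entry_offset` (years), `unit_id`,
#'   `study_year`, `population`.
#' @export
extract_intervals <- function(recs, population = NULL,
                              drop_short_censored = TRUE) {
  f <- recs$females
  if (!is.null(population)) f <- f[f$population %in% population, , drop = FALSE]
  b <- recs$births[recs$births$mother_id %in% f$female_id, , drop = FALSE]
  ft <- recs$fates

  death_of <- function(infant_id) {
    i <- match(infant_id, ft$infant_id)
    if (is.na(i)) as.Date(NA) else ft$death_date[i]
  }

  rows <- list()
  for (k in seq_len(nrow(f))) {
    mother <- f[k, ]
    mb <- b[b$mother_id == mother$female_id, , drop = FALSE]
    if (!nrow(mb)) next
    mb <- mb[order(mb$birth_date), , drop = FALSE]
    for (j in seq_len(nrow(mb))) {
      open_birth <- mb$birth_date[j]
      open_death <- death_of(mb$infant_id[j])
      if (j < nrow(mb)) {
        close_birth <- mb$birth_date[j + 1L]
        duration <- as.numeric(close_birth - open_birth) / DAYS_PER_YEAR
        if (duration < 0) {
          stop("negative interbirth interval for mother ", mother$female_id,
               call. = FALSE)
        }
        # opening infant must outlive the interval
        if (!is.na(open_death) && open_death < close_birth) next
        closed <- TRUE
      } else {
        duration <- as.numeric(mother$depart_date - open_birth) / DAYS_PER_YEAR
        if (duration < 0) {
          stop("departure precedes final birth for mother ", mother$female_id,
               call. = FALSE)
        }
        open_death_age <- if (is.na(open_death)) Inf else
          as.numeric(open_death - open_birth) / DAYS_PER_YEAR
        if (open_death_age < min(1, duration)) next
        closed <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mother_id = mother$female_id,
        start_birth_date = open_birth,
        maternal_age_at_start = age_at(mother, open_birth),
        duration = duration,
        closed = closed,
        unit_id = mother$unit_id,
        study_year = as.integer(format(open_birth, "%Y")),
        population = mother$population,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mother_id = character(0), start_birth_date = as.Date(character(0)),
    maternal_age_at_start = numeric(0), duration = numeric(0),
    closed = logical(0), unit_id = character(0), study_year = integer(0),
    population = character(0), stringsAsFactors = FALSE)
  closed_durs <- out$duration[out$closed]
  out$entry_offset <- if (length(closed_durs)) min(closed_durs) else 0
  if (drop_short_censored) {
    out <- out[out$closed | out$duration >= out$entry_offset, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("ibi_data", "data.frame")
  out
}

#' Attribute a cause of death to one infant
#'
#' Deterministic precedence rule over the evidence channels:
#' \enumerate{
#'   \item \emph{maternal death} if the infant died within the 90 days
#'     following its mother's disappearance;
#'   \item \emph{infanticide} if (chacma) a male attack was observed or
#'     inferred from injuries, or (gelada) the death fell within the 180
#'     days following a male takeover in the infant's unit;
#'   \item \emph{injury or illness} if injury or clear ill health was
#'     observed within the 30 days before death;
#'   \item \emph{unknown} otherwise.
#' }
#'
#' @param fate one row of the fates table, with a `death_date`.
#' @param takeovers the takeovers table.
#' @param population `"chacma"` or `"gelada"` (any label other than
#'   `"gelada"` uses the observed-attack rule).
#' @param unit_id the infant's unit at death (required for the gelada
#'   takeover rule).
#' @return A list of class `cause_of_death` with elements `category` and
#'   `evidence`.
#' @export
attribute_cause <- function(fate, takeovers, population, unit_id = NULL) {
  if (is.na(fate$death_date)) {
    stop("attribute_cause requires a death_date", call. = FALSE)
  }
  res <- function(category, evidence) {
    structure(list(category = category, evidence = evidence),
              class = "cause_of_death")
  }
  dd <- fate$death_date

  if (!is.null(fate$mother_disappearance_date) &&
      !is.na(fate$mother_disappearance_date)) {
    lag <- as.numeric(dd - fate$mother_disappearance_date)
    if (lag >= 0 && lag <= 90) return(res("maternal_death", "orphan_window"))
  }

  if (identical(population, "gelada")) {
    if (is.null(unit_id) || is.na(unit_id)) {
      stop("gelada cause attribution requires the infant's unit_id",
           call. = FALSE)
    }
    to <- takeovers[takeovers$unit_id == unit_id, , drop = FALSE]
    if (nrow(to)) {
      lags <- as.numeric(dd - to$takeover_date)
      if (any(lags >= 0 & lags <= 180)) {
        return(res("infanticide", "takeover_window"))
      }
    }
  } else {
    if (isTRUE(fate$observed_attack)) {
      return(res("infanticide", "attack_observed"))
    }
  }

  if (isTRUE(fate$illness_or_injury_observed) &&
      !is.na(fate$illness_observation_date)) {
    lag <- as.numeric(dd - fate$illness_observation_date)
    if (lag >= 0 && lag <= 30) return(res("injury_or_illness",
                                          "health_observation"))
  }
  res("unknown", "none")
}

#' Build the infant-survival dataset (to one year of age)
#'
#' One record per born infant, observed from birth to the earliest of
#' death, censoring and exact age one. Deaths within the first year get a
#' cause via [attribute_cause()].
#'
#' @param recs a `demog_records` collection.
#' @param population optional population subset.
#' @param missing_fates `"error"` (default) or `"censor"`: infants with
#'   no fate record are either an error or censored at their mother's
#'   departure (capped at age one), with a warning listing them.
#' @return A data frame of class `infant_data` with columns `infant_id`,
#'   `mother_id`, `maternal_age_at_birth`, `time_observed` (years, in
#'   (0, 1]), `died`, `cause`, `birth_year`, `unit_id`, `population`.
#' @export
build_infant_dataset <- function(recs, population = NULL,
                                 missing_fates = c("error", "censor")) {
  missing_fates <- match.arg(missing_fates)
  f <- recs$females
  if (!is.null(population)) f <- f[f$population %in% population, , drop = FALSE]
  b <- recs$births[recs$births$mother_id %in% f$female_id, , drop = FALSE]
  ft <- recs$fates

  no_fate <- setdiff(b$infant_id, ft$infant_id)
  if (length(no_fate)) {
    msg <- paste("infants without a fate record:",
                 paste(no_fate, collapse = ", "))
    if (missing_fates == "error") stop(msg, call. = FALSE)
    warning(msg, "; censored at mother's departure", call. = FALSE)
  }

  half_day <- 0.5 / DAYS_PER_YEAR
  rows <- vector("list", nrow(b))
  for (k in seq_len(nrow(b))) {
    birth <- b[k, ]
    mi <- match(birth$mother_id, f$female_id)
    mother <- f[mi, ]
    fi <- match(birth$infant_id, ft$infant_id)
    if (is.na(fi)) {
      end_date <- mother$depart_date
      death_age <- Inf
    } else {
      fate <- ft[fi, ]
      end_date <- if (is.na(fate$death_date)) fate$censor_date else
        fate$death_date
      death_age <- if (is.na(fate$death_date)) Inf else
        as.numeric(fate$death_date - birth$birth_date) / DAYS_PER_YEAR
    }
    obs_age <- as.numeric(end_date - birth$birth_date) / DAYS_PER_YEAR
    time_observed <- max(min(1, obs_age), half_day)
    died <- is.finite(death_age) && death_age <= 1
    cause <- NA_character_
    if (died) {
      cause <- attribute_cause(ft[fi, ], recs$takeovers, mother$population,
                               unit_id = mother$unit_id)$category
      time_observed <- max(min(1, death_age), half_day)
    } else if (time_observed < 1) {
      cause <- "censored"
    }
    rows[[k]] <- data.frame(
      infant_id = birth$infant_id,
      mother_id = birth$mother_id,
      maternal_age_at_birth = age_at(mother, birth$birth_date),
      time_observed = time_observed,
      died = died,
      cause = cause,
      birth_year = as.integer(format(birth$birth_date, "%Y")),
      unit_id = mother$unit_id,
      population = mother$population,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    infant_id = character(0), mother_id = character(0),
    maternal_age_at_birth = numeric(0), time_observed = numeric(0),
    died = logical(0), cause = character(0), birth_year = integer(0),
    unit_id = character(0), population = character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("infant_data", "data.frame")
  out
}
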