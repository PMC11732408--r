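# Canonical data model for longitudinal female demographic records.
#
# A record collection is a list of four data frames sharing one calendar
# convention (Date, ISO-8601) and one year length (365.25 days):
#   females:  one row per study female (entry under left truncation,
#             departure by death or censoring)
#   births:   one row per observed infant birth
#   fates:    one row per infant, death or censoring with evidence fields
#   takeovers: one row per leader-male replacement in a social unit

DAYS_PER_YEAR <- 365.25

.female_cols <- c("female_id", "population", "birth_date", "birth_date_known",
                  "entry_date", "depart_date", "depart_type", "unit_id")
.birth_cols <- c("infant_id", "mother_id", "birth_date", "date_accuracy_days")
.fate_cols <- c("infant_id", "death_date", "censor_date", "observed_attack",
                "illness_or_injury_observed", "illness_observation_date",
                "mother_disappearance_date")
.takeover_cols <- c("unit_id", "takeover_date")

.parse_dates <- function(df, cols, file) {
  for (col in intersect(cols, names(df))) {
    raw <- as.character(df[[col]])
    raw[!is.na(raw) & raw == ""] <- NA
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("%s: unparseable date in column '%s', line(s) %s",
                   file, col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df
}

.require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 file, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = "character")
}

.as_logical <- function(x) {
  out <- rep(NA, length(x))
  out[!is.na(x) & tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[!is.na(x) & tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  as.logical(out)
}

#' Read a demographic record collection from delimited text files
#'
#' Reads the four canonical comma-delimited tables (`females.csv`,
#' `births.csv`, `infant_fates.csv`, `takeovers.csv`) from a directory,
#' parses all dates to the ISO-8601 calendar, cross-references the tables
#' and validates every typed invariant.
#'
#' @param data_dir directory containing the four CSV files.
#' @param schema_version schema label; only `"1"` is currently defined.
#' @return A validated object of class `demog_records`: a list with
#'   elements `females`, `births`, `fates`, `takeovers`.
#' @details Empty strings are read as missing. Validation errors name the
#'   offending file, column and rows. An empty births (or fates, or
#'   takeovers) file with a valid header is legal.
#' @seealso [validate_records()], [write_records()], [age_at()]
#' @export
read_records <- function(data_dir, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown schema_version: ", schema_version, call. = FALSE)
  }
  paths <- file.path(data_dir, c("females.csv", "births.csv",
                                 "infant_fates.csv", "takeovers.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  females <- .require_cols(.read_csv(paths[1]), .female_cols, "females.csv")
  births <- .require_cols(.read_csv(paths[2]), .birth_cols, "births.csv")
  fates <- .require_cols(.read_csv(paths[3]), .fate_cols, "infant_fates.csv")
  takeovers <- .require_cols(.read_csv(paths[4]), .takeover_cols,
                             "takeovers.csv")

  females <- .parse_dates(females, c("birth_date", "entry_date",
                                     "depart_date"), "females.csv")
  females$birth_date_known <- .as_logical(females$birth_date_known)
  births <- .parse_dates(births, "birth_date", "births.csv")
  births$date_accuracy_days <- as.numeric(births$date_accuracy_days)
  fates <- .parse_dates(fates, c("death_date", "censor_date",
                                 "illness_observation_date",
                                 "mother_disappearance_date"),
                        "infant_fates.csv")
  fates$observed_attack <- .as_logical(fates$observed_attack)
  fates$illness_or_injury_observed <- .as_logical(fates$illness_or_injury_observed)
  takeovers <- .parse_dates(takeovers, "takeover_date", "takeovers.csv")

  recs <- structure(list(females = females, births = births, fates = fates,
                         takeovers = takeovers),
                    class = "demog_records")
  validate_records(recs)
  recs
}

#' Assemble and validate a record collection from data frames
#'
#' Constructor used by the simulator and by tests; applies the same
#' validation as [read_records()].
#'
#' @param females,births,fates,takeovers data frames with the canonical
#'   columns (dates as `Date`).
#' @return A `demog_records` object.
#' @export
demog_records <- function(females, births, fates, takeovers) {
  recs <- structure(list(females = females, births = births, fates = fates,
                         takeovers = takeovers),
                    class = "demog_records")
  validate_records(recs)
  recs
}

#' Validate the typed invariants of a record collection
#'
#' Checks, for every record: entry on or after birth, departure on or
#' after entry, a defined departure type; every birth resolves to a known
#' mother and falls inside her plausible reproductive window; every fate
#' carries exactly one of death date / censor date with observation dates
#' not after the death.
#'
#' @param recs a `demog_records` object.
#' @param min_maturation_age years; earliest allowed age at a birth event.
#' @return `recs`, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_records <- function(recs, min_maturation_age = 3.5) {
  f <- recs$females
  problems <- character(0)
  say <- function(fmt, idx) {
    if (length(idx)) {
      problems <<- c(problems, sprintf(fmt, paste(idx, collapse = ", ")))
    }
  }
  if (anyDuplicated(f$female_id)) {
    problems <- c(problems, "females: duplicated female_id")
  }
  say("females: entry_date before birth_date in row(s) %s",
      which(!is.na(f$entry_date) & !is.na(f$birth_date) &
              f$entry_date < f$birth_date))
  say("females: depart_date before entry_date in row(s) %s",
      which(!is.na(f$depart_date) & !is.na(f$entry_date) &
              f$depart_date < f$entry_date))
  say("females: depart_type must be 'death' or 'censored' in row(s) %s",
      which(is.na(f$depart_type) | !f$depart_type %in% c("death", "censored")))
  say("females: missing birth/entry/depart date in row(s) %s",
      which(is.na(f$birth_date) | is.na(f$entry_date) | is.na(f$depart_date)))

  b <- recs$births
  if (nrow(b)) {
    dangling <- which(!b$mother_id %in% f$female_id)
    say("births: mother_id not found among females in row(s) %s", dangling)
    idx <- match(b$mother_id, f$female_id)
    ok <- !is.na(idx)
    mother_birth <- f$birth_date[idx]
    mother_depart <- f$depart_date[idx]
    early <- which(ok & as.numeric(b$birth_date - mother_birth) / DAYS_PER_YEAR <
                     min_maturation_age)
    say("births: birth before mother's minimum maturation age in row(s) %s",
        early)
    late <- which(ok & b$birth_date > mother_depart)
    say("births: birth after mother's departure in row(s) %s", late)
    say("births: negative date_accuracy_days in row(s) %s",
        which(!is.na(b$date_accuracy_days) & b$date_accuracy_days < 0))
  }

  ft <- recs$fates
  if (nrow(ft)) {
    both <- which(!is.na(ft$death_date) & !is.na(ft$censor_date))
    say("infant_fates: both death_date and censor_date set in row(s) %s", both)
    neither <- which(is.na(ft$death_date) & is.na(ft$censor_date))
    say("infant_fates: neither death_date nor censor_date set in row(s) %s",
        neither)
    obs_late <- which(!is.na(ft$death_date) & !is.na(ft$illness_observation_date) &
                        ft$illness_observation_date > ft$death_date)
    say("infant_fates: illness observation after death in row(s) %s", obs_late)
    say("infant_fates: infant_id not found among births in row(s) %s",
        which(!ft$infant_id %in% b$infant_id))
  }

  if (length(problems)) {
    stop(paste(c("invalid record collection:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  invisible(recs)
}

#' Write a record collection to the canonical CSV files
#'
#' Inverse of [read_records()]: round-tripping a valid collection through
#' `write_records()` and `read_records()` is the identity on all fields.
#'
#' @param recs a `demog_records` object.
#' @param data_dir output directory (created if needed).
#' @param force overwrite existing files.
#' @return `data_dir`, invisibly.
#' @export
write_records <- function(recs, data_dir, force = FALSE) {
  dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(females = "females.csv", births = "births.csv",
             fates = "infant_fates.csv", takeovers = "takeovers.csv")
  for (nm in names(files)) {
    path <- file.path(data_dir, files[[nm]])
    if (file.exists(path) && !force) {
      stop("refusing to overwrite ", path, " (use force = TRUE)",
           call. = FALSE)
    }
    df <- recs[[nm]]
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(data_dir)
}

#' Age of a female at a calendar date
#'
#' @param female one row of the `females` table (or any list with a
#'   `birth_date` element).
#' @param date a `Date` (or vector of dates) on or after the birth date.
#' @return Age in years, using a fixed 365.25-day year.
#' @export
age_at <- function(female, date) {
  date <- as.Date(date)
  if (any(date < female$birth_date)) {
    stop("date precedes the female's birth date", call. = FALSE)
  }
  as.numeric(date - as.Date(female$birth_date)) / DAYS_PER_YEAR
}

#' @export
print.demog_records <- function(x, ...) {
  pops <- unique(x$females$population)
  cat("Demographic record collection\n")
  cat(sprintf("  females:   %d (%s)\n", nrow(x$females),
              paste(pops, collapse = ", ")))
  cat(sprintf("  births:    %d\n", nrow(x$births)))
  cat(sprintf("  fates:     %d (%d deaths)\n", nrow(x$fates),
              sum(!is.na(x$fates$death_date))))
  cat(sprintf("  takeovers: %d\n", nrow(x$takeovers)))
  invisible(x)
}
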