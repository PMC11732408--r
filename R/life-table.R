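# Yearly age-class life tables under staggered entry (left truncation)
# and right censoring, plus life-table summaries and age-class binomial
# regressions of fertility and mortality.

.age_years <- function(from, to) as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_YEAR

# classes a female contributes risk time to, under the individual-count
# convention: first = floor(entry age); last = floor(depart age) for
# deaths, else the last class actually entered before censoring
.risk_classes <- function(entry_age, depart_age, death) {
  first <- floor(entry_age)
  if (death) {
    last <- floor(depart_age)
  } else {
    fl <- floor(depart_age)
    last <- if (depart_age == fl) fl - 1L else fl
  }
  if (last < first) return(integer(0))
  seq.int(first, last)
}

#' Build a yearly age-class life table
#'
#' Divides each female's observed lifespan into yearly age classes
#' (0–1, 1–2, ...). A female contributes to class \eqn{[x, x+1)} only
#' while under observation, so entry after birth (study onset) gives left
#' truncation and departure without death gives right censoring. All
#' observed births count towards fertility, including births hastened by
#' a previous infant's death.
#'
#' Per class: `q_x` = deaths / females at risk; `l_x` = cumulative
#' survivorship from birth (`l_0 = 1`); `m_x` = births / females at risk;
#' `L_x` = person-years lived in the class, `(l_x + l_{x+1})/2`.
#' Classes with zero risk carry `NA` (undefined), never zero, rates.
#'
#' @param recs a `demog_records` collection.
#' @param population optional population label to subset on.
#' @param convention `"count"` (default): denominators are the number of
#'   females under observation at any point in the class;
#'   `"person_years"`: denominators are exact person-years of observation
#'   in the class (rates are then occurrence/exposure, not probabilities).
#' @return A data frame of class `life_table` with columns `x`,
#'   `n_risk_survival`, `n_deaths`, `q_x`, `l_x`, `n_risk_fertility`,
#'   `n_births`, `m_x`, `L_x`.
#' @export
build_life_table <- function(recs, population = NULL,
                             convention = c("count", "person_years")) {
  convention <- match.arg(convention)
  f <- recs$females
  if (!is.null(population)) f <- f[f$population %in% population, , drop = FALSE]
  if (!nrow(f)) stop("no females to tabulate", call. = FALSE)
  b <- recs$births[recs$births$mother_id %in% f$female_id, , drop = FALSE]

  entry_age <- .age_years(f$birth_date, f$entry_date)
  depart_age <- .age_years(f$birth_date, f$depart_date)
  death <- f$depart_type == "death"

  max_class <- max(floor(depart_age), 0)
  x <- 0:max_class
  n_classes <- length(x)
  n_risk <- numeric(n_classes)
  exposure <- numeric(n_classes)
  n_deaths <- integer(n_classes)

  for (k in seq_len(nrow(f))) {
    cls <- .risk_classes(entry_age[k], depart_age[k], death[k])
    n_risk[cls + 1L] <- n_risk[cls + 1L] + 1L
    for (cx in cls) {
      lo <- max(cx, entry_age[k]); hi <- min(cx + 1, depart_age[k])
      exposure[cx + 1L] <- exposure[cx + 1L] + max(hi - lo, 0)
    }
    if (death[k]) {
      dc <- floor(depart_age[k]) + 1L
      n_deaths[dc] <- n_deaths[dc] + 1L
    }
  }
  if (any(n_deaths > 0 & n_risk == 0)) {
    stop("age class with deaths but nobody at risk: inconsistent records",
         call. = FALSE)
  }

  n_births <- integer(n_classes)
  if (nrow(b)) {
    mi <- match(b$mother_id, f$female_id)
    observed <- b$birth_date >= f$entry_date[mi] & b$birth_date <= f$depart_date[mi]
    bage <- floor(.age_years(f$birth_date[mi], b$birth_date))
    for (k in which(observed)) {
      n_births[bage[k] + 1L] <- n_births[bage[k] + 1L] + 1L
    }
  }

  denom <- if (convention == "count") n_risk else exposure
  q_x <- ifelse(denom > 0, n_deaths / denom, NA_real_)
  m_x <- ifelse(denom > 0, n_births / denom, NA_real_)

  l_x <- numeric(n_classes)
  l_x[1] <- 1
  for (i in seq_len(n_classes - 1L)) {
    l_x[i + 1L] <- if (is.na(q_x[i])) NA_real_ else l_x[i] * (1 - q_x[i])
  }
  l_end <- if (is.na(q_x[n_classes])) NA_real_ else
    l_x[n_classes] * (1 - q_x[n_classes])
  l_next <- c(l_x[-1L], l_end)
  L_x <- (l_x + l_next) / 2

  out <- data.frame(x = x, n_risk_survival = denom, n_deaths = n_deaths,
                    q_x = q_x, l_x = l_x, n_risk_fertility = denom,
                    n_births = n_births, m_x = m_x, L_x = L_x)
  attr(out, "population") <- if (is.null(population)) "all" else
    paste(population, collapse = "+")
  attr(out, "convention") <- convention
  class(out) <- c("life_table", "data.frame")
  out
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat(sprintf("Yearly life table (%s; %s convention)\n",
              attr(x, "population"), attr(x, "convention")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Expected lifetime reproduction from a life table
#'
#' Expected number of offspring for a female conditional on surviving to
#' `conditioning_age`: \eqn{\sum_{x \ge c} (l_x / l_c)\, m_x}. With
#' `conditioning_age = 0` this is the expectation at birth.
#'
#' @param lt a `life_table`.
#' @param conditioning_age integer age class \eqn{c} (years).
#' @return Expected offspring count (scalar).
#' @export
expected_lifetime_reproduction <- function(lt, conditioning_age = 0) {
  i <- match(conditioning_age, lt$x)
  if (is.na(i)) stop("conditioning_age outside the table", call. = FALSE)
  l_c <- lt$l_x[i]
  if (is.na(l_c) || l_c <= 0) {
    stop("survivorship to the conditioning age is zero or undefined",
         call. = FALSE)
  }
  sel <- lt$x >= conditioning_age & !is.na(lt$m_x) & !is.na(lt$l_x)
  sum(lt$l_x[sel] / l_c * lt$m_x[sel])
}

#' Age-class binomial regression of fertility or mortality
#'
#' Pools per-class counts from one or more populations and fits a
#' binomial regression of the per-class proportion on standardized age,
#' age squared, population, and age-by-population interactions, by
#' maximum a-posteriori estimation with independent normal(0, 2.5)
#' coefficient priors. Standard errors come from the curvature (observed
#' information) at the optimum.
#'
#' Coefficients are on the standardized-age scale
#' (`(x - center) / scale`, computed over represented classes), so only
#' their signs and relative shapes — not raw magnitudes — are comparable
#' across datasets with different age structures.
#'
#' @param tables a named list of `life_table` objects, one per
#'   population (one table is allowed; population terms are then absent).
#' @param outcome `"births"` or `"deaths"`.
#' @param prior_sd prior standard deviation for all coefficients.
#' @return Object of class `ageclass_glm` with elements `coefficients`,
#'   `se`, `vcov`, `loglik`, `data`, `scaling`, `converged`.
#' @export
fit_ageclass_glm <- function(tables, outcome = c("births", "deaths"),
                             prior_sd = 2.5) {
  outcome <- match.arg(outcome)
  if (inherits(tables, "life_table")) tables <- list(pop = tables)
  dat <- do.call(rbind, lapply(names(tables), function(nm) {
    lt <- tables[[nm]]
    data.frame(population = nm, x = lt$x,
               size = lt$n_risk_survival,
               successes = if (outcome == "births") lt$n_births else lt$n_deaths)
  }))
  dat <- dat[dat$size > 0, , drop = FALSE]
  if (nrow(dat) < 2) stop("need at least 2 age classes with risk", call. = FALSE)
  over <- dat$successes > dat$size
  if (any(over)) {
    warning("classes with more successes than individuals at risk capped")
    dat$successes[over] <- dat$size[over]
  }

  center <- mean(dat$x); scale <- stats::sd(dat$x)
  z <- (dat$x - center) / scale
  X <- cbind(intercept = 1, age = z, age2 = z^2)
  if (length(tables) > 1) {
    pop <- as.integer(factor(dat$population, levels = names(tables))) - 1L
    X <- cbind(X, pop = pop, `age:pop` = z * pop, `age2:pop` = z^2 * pop)
  }

  negpost <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- sum(dat$successes * stats::plogis(eta, log.p = TRUE) +
                (dat$size - dat$successes) * stats::plogis(-eta, log.p = TRUE))
    -ll + sum(beta^2) / (2 * prior_sd^2)
  }
  fit <- stats::optim(rep(0, ncol(X)), negpost, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, ncol(X)) else sqrt(diag(vc))
  beta <- stats::setNames(fit$par, colnames(X))
  structure(list(coefficients = beta,
                 se = stats::setNames(se, colnames(X)),
                 vcov = vc,
                 loglik = -negpost(fit$par),
                 data = dat, outcome = outcome,
                 scaling = c(center = center, scale = scale),
                 prior_sd = prior_sd,
                 converged = fit$convergence == 0),
            class = "ageclass_glm")
}

#' @export
print.ageclass_glm <- function(x, ...) {
  cat(sprintf("Age-class binomial regression (outcome: %s)\n", x$outcome))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.ageclass_glm <- function(object, ...) object$coefficients
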