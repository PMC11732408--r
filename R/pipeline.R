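# End-to-end pipeline: records -> intervals -> infants -> life table ->
# PrR -> interval hazard fit -> infant hazard fit -> cause models, with
# a manifest and machine-readable outputs per stage.

.log_stage <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

.fit_to_list <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       beta = if (is.matrix(fit$beta)) as.data.frame(fit$beta) else
         as.list(fit$beta),
       baseline_weights = as.numeric(fit$baseline_weights),
       boundary_knots = fit$baseline_basis$boundary_knots,
       internal_knots = fit$baseline_basis$internal_knots,
       tve = !is.null(fit$tve_basis),
       loglik = fit$loglik, n_events = fit$n_events,
       n_censored = fit$n_censored, converged = fit$converged,
       age_scaling = as.list(fit$age_scaling), seed = fit$seed)
}

#' Run the full demographic analysis pipeline
#'
#' Executes, per population: interval extraction, infant-dataset
#' construction, life-table building, the PrR simulation test, the
#' interbirth-interval hazard fit, the infant-survival hazard fit and
#' the four cause-specific mortality models; writes CSV tables, JSON fit
#' reports, a human-readable summary and a manifest (config, package
#' version, output checksums).
#'
#' @param output_dir directory for outputs (created if needed).
#' @param data_dir directory with the four canonical CSV files; mutually
#'   exclusive with `preset`.
#' @param preset a simulation preset name ([sim_preset()]) used instead
#'   of on-disk data.
#' @param populations population labels to analyse (default: all found).
#' @param seed seed for simulation and the PrR null.
#' @param n_sim PrR null replicates.
#' @param tve fit the interval model with time-varying age effects.
#' @param random_intercepts grouping columns for the hazard models.
#' @param force overwrite existing outputs.
#' @param quiet suppress stage logging.
#' @return (Invisibly) a list with per-population results and the
#'   manifest.
#' @export
run_pipeline <- function(output_dir, data_dir = NULL, preset = NULL,
                         populations = NULL, seed = 1, n_sim = 1000,
                         tve = FALSE, random_intercepts = NULL,
                         force = FALSE, quiet = FALSE) {
  if (is.null(data_dir) == is.null(preset)) {
    stop("supply exactly one of data_dir or preset", call. = FALSE)
  }
  if (dir.exists(output_dir) &&
      length(list.files(output_dir)) > 0 && !force) {
    stop("output_dir is non-empty (use force = TRUE)", call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  result <- tryCatch({
    if (!is.null(preset)) {
      .log_stage(quiet, stage, "simulating preset '", preset, "'")
      sim <- simulate_population(sim_preset(preset), seed = seed)
      recs <- sim$records
    } else {
      .log_stage(quiet, stage, "reading records from ", data_dir)
      recs <- read_records(data_dir)
    }
    if (is.null(populations)) {
      populations <- unique(recs$females$population)
    }

    write_csv_out <- function(df, file) {
      out <- as.data.frame(df)
      for (col in names(out)) {
        if (inherits(out[[col]], "Date")) {
          out[[col]] <- format(out[[col]], "%Y-%m-%d")
        }
      }
      utils::write.csv(out, file.path(output_dir, file), row.names = FALSE,
                       na = "")
    }
    write_json_out <- function(x, file) {
      jsonlite::write_json(x, file.path(output_dir, file),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    summary_list <- list(seed = seed)
    for (pop in populations) {
      stage <- paste0("intervals:", pop)
      .log_stage(quiet, stage, "extracting interbirth intervals")
      intervals <- extract_intervals(recs, pop)
      write_csv_out(intervals, paste0("intervals_", pop, ".csv"))

      stage <- paste0("infants:", pop)
      infants <- build_infant_dataset(recs, pop, missing_fates = "censor")
      write_csv_out(infants, paste0("infants_", pop, ".csv"))

      stage <- paste0("lifetable:", pop)
      lt <- build_life_table(recs, pop)
      write_csv_out(lt, paste0("lifetable_", pop, ".csv"))

      stage <- paste0("prr:", pop)
      .log_stage(quiet, stage, "PrR simulation test (", n_sim, " replicates)")
      prr <- prr_test(lt, n_sim = n_sim, seed = seed)
      write_json_out(list(B = prr$B, M = prr$M,
                          post_repro_start = prr$post_repro_start,
                          T_B = prr$T_B, T_M = prr$T_M, prr = prr$prr,
                          n_sim = prr$n_sim, n_females = prr$n_females,
                          p_value = prr$p_value, seed = prr$seed),
                     paste0("prr_", pop, ".json"))

      stage <- paste0("ibi-fit:", pop)
      .log_stage(quiet, stage, "interval hazard model (tve = ", tve, ")")
      ibi_fit <- fit_hazard_model(
        intervals, spec = hazard_model_spec(
          tve = tve, random_intercepts = random_intercepts), seed = seed)
      write_json_out(.fit_to_list(ibi_fit), paste0("ibi_fit_", pop, ".json"))

      stage <- paste0("infant-fit:", pop)
      .log_stage(quiet, stage, "infant survival hazard model")
      infant_fit <- fit_hazard_model(
        infants, spec = hazard_model_spec(
          random_intercepts = random_intercepts), seed = seed)
      write_json_out(.fit_to_list(infant_fit),
                     paste0("infant_fit_", pop, ".json"))

      stage <- paste0("causes:", pop)
      .log_stage(quiet, stage, "cause-specific mortality models")
      cms <- fit_cause_models(infants)
      decomp <- mortality_decomposition(infants)
      write_json_out(
        list(models = lapply(cms, function(m)
          list(cause = m$cause, beta = as.list(m$beta), se = as.list(m$se),
               n_cases = m$n_cases, n_total = m$n_total)),
          decomposition = list(
            overall = as.list(decomp$overall),
            by_tertile = as.data.frame(decomp$by_tertile),
            boundaries = as.numeric(decomp$boundaries),
            n_deaths = decomp$n_deaths)),
        paste0("causes_", pop, ".json"))

      summary_list[[pop]] <- list(
        n_females = sum(recs$females$population == pop),
        n_intervals = nrow(intervals),
        n_closed = sum(intervals$closed),
        mean_closed_ibi = if (any(intervals$closed))
          mean(intervals$duration[intervals$closed]) else NA,
        entry_offset = if (nrow(intervals)) intervals$entry_offset[1] else NA,
        n_infants = nrow(infants),
        first_year_mortality = mean(infants$died[infants$time_observed >= 1 |
                                                   infants$died]),
        prr = prr$prr, prr_p_value = prr$p_value,
        lifetime_reproduction_at_birth = tryCatch(
          expected_lifetime_reproduction(lt, 0), error = function(e) NA),
        ibi_loglik = ibi_fit$loglik,
        infant_fit_beta = if (is.matrix(infant_fit$beta)) NULL else
          as.list(infant_fit$beta))
    }

    stage <- "manifest"
    write_json_out(summary_list, "summary.json")
    files <- setdiff(list.files(output_dir), "manifest.json")
    manifest <- list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      package_version = as.character(utils::packageVersion("senodemog")),
      config = list(data_dir = data_dir, preset = preset,
                    populations = populations, seed = seed, n_sim = n_sim,
                    tve = tve, random_intercepts = random_intercepts),
      outputs = lapply(stats::setNames(files, files), function(f)
        unname(tools::md5sum(file.path(output_dir, f)))))
    write_json_out(manifest, "manifest.json")
    list(summary = summary_list, manifest = manifest,
         output_dir = output_dir)
  }, error = function(e) {
    marker <- file.path(output_dir, "failed")
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)), marker)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
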