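# End-to-end orchestration: simulate (or read) -> classify -> link ->
# ascertain -> design -> fit -> summarize, with fixed file contracts and
# a machine-readable run manifest.

#' Configuration of a pipeline run
#'
#' Either a `simulate` block (a [sim_config()]) or the four input CSV
#' paths must be supplied.
#'
#' @param simulate A [sim_config()] for fully synthetic runs, or `NULL`.
#' @param monitor_csv,sites_csv,zips_csv,visits_csv,met_csv Input paths
#'   (ignored in simulate mode).
#' @param classifier A [classifier_config()].
#' @param buffer_km Linkage buffer, km (primary 50; sensitivity 15).
#' @param outcomes Outcome names to analyse (subset of the built-ins).
#' @param lags Lags to profile (subset of 0..5).
#' @param adjust_pollutants Add PM2.5/NO2/O3 linear terms to the model.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest; in simulate mode it
#'   overrides `simulate$seed` so one knob governs all randomness.
#' @param write_sets Also write the per-outcome, per-lag matched-set CSVs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulate = NULL,
                       monitor_csv = NULL, sites_csv = NULL, zips_csv = NULL,
                       visits_csv = NULL, met_csv = NULL,
                       classifier = classifier_config(),
                       buffer_km = 50, outcomes = c("RD", "CVD"),
                       lags = 0:5, adjust_pollutants = FALSE,
                       out_dir = tempfile("dustcase_run_"),
                       seed = NULL, write_sets = FALSE) {
  if (buffer_km <= 0) abort("`buffer_km` must be > 0.")
  if (!all(lags %in% 0:5)) abort("`lags` must be a subset of 0..5.")
  bad <- setdiff(outcomes, names(outcome_definitions()))
  if (length(bad)) {
    abort(paste0("Unknown outcome(s): ", paste(bad, collapse = ", "), "."))
  }
  if (is.null(simulate)) {
    paths <- c(monitor_csv, sites_csv, zips_csv, visits_csv, met_csv)
    if (length(paths) < 5) {
      abort("Supply either `simulate` or all five input CSV paths.")
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
    if (!is.null(seed)) simulate$seed <- as.integer(seed)
  }
  structure(
    list(
      simulate = simulate, monitor_csv = monitor_csv, sites_csv = sites_csv,
      zips_csv = zips_csv, visits_csv = visits_csv, met_csv = met_csv,
      classifier = classifier, buffer_km = buffer_km, outcomes = outcomes,
      lags = as.integer(lags), adjust_pollutants = adjust_pollutants,
      out_dir = out_dir, seed = seed %||% (simulate$seed %||% NA_integer_),
      write_sets = write_sets
    ),
    class = "run_config"
  )
}

# pre-aggregate visits to one weighted case per (zip, date): identical
# sets collapse here already, which keeps the design stage linear in the
# number of distinct case days rather than the number of visits
aggregate_cases <- function(cases) {
  cases |>
    dplyr::count(.data$zip_id, .data$site_id, .data$admission_date,
                 name = "weight") |>
    dplyr::mutate(visit_id = sprintf("S%06d", dplyr::row_number()))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the input streams, classifies dust storm days,
#' links ZIP units to monitors under the buffer, ascertains visits per
#' outcome, builds the customized time-stratified strata, fits the
#' single-lag conditional logistic models for every requested lag, and
#' writes all artifacts plus a run manifest to `config$out_dir`.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list: results (lag-OR table), labels, linkage,
#'   comparison_table, site_summary, manifest, paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))

  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic streams (seed %d)",
        config$simulate$seed)
    study <- sim_study(config$simulate)
    records <- study$records
    sites <- study$sites
    zips <- study$zip_units
    visits <- study$visits
    met <- study$met
    write_output_csv(records, config$out_dir, "monitor.csv")
    write_output_csv(sites, config$out_dir, "sites.csv")
    write_output_csv(zips, config$out_dir, "zips.csv")
    write_output_csv(visits, config$out_dir, "visits.csv")
    period <- c(config$simulate$date_start, config$simulate$date_end)
  } else {
    records <- read_monitor_csv(config$monitor_csv)
    sites <- read_sites_csv(config$sites_csv)
    zips <- read_zips_csv(config$zips_csv)
    visits <- read_visits_csv(config$visits_csv)
    met <- read_met_csv(config$met_csv)
    period <- range(c(records$date, visits$admission_date))
  }

  say("stage classify: %d monitor records", nrow(records))
  labels <- classify_series(records, config$classifier,
                            date_start = period[1], date_end = period[2])
  n_dust <- sum(labels$dust == 1, na.rm = TRUE)
  write_output_csv(
    dplyr::select(labels, "site_id", "date", dust_indicator = "dust"),
    config$out_dir, "labels.csv"
  )
  write_output_csv(labels, config$out_dir, "labels_trace.csv")

  say("stage link: buffer %.0f km", config$buffer_km)
  linkage <- assign_sites(zips, sites, buffer_km = config$buffer_km)
  write_output_csv(linkage, config$out_dir, "linkage.csv")

  strata <- build_strata(period[1], period[2])
  holidays <- us_federal_holidays(
    seq(as.integer(format(period[1], "%Y")) - 1,
        as.integer(format(period[2], "%Y")))
  )

  results <- list()
  counts <- list()
  all_cases <- list()
  for (oc in config$outcomes) {
    cases <- select_visits(visits, oc, linkage, quiet = quiet,
                           warn_era_conflicts = FALSE)
    all_cases[[oc]] <- cases
    counts[[oc]] <- list(
      visits_in = attr(cases, "n_input"),
      matched = attr(cases, "n_matched"),
      kept = attr(cases, "n_kept"),
      dropped_unlinked = attr(cases, "n_matched") - attr(cases, "n_kept")
    )
    if (nrow(cases) == 0) {
      say("outcome %s: no analysable cases; skipped", oc)
      next
    }
    agg <- aggregate_cases(cases)
    say("outcome %s: %d visits -> %d weighted case days", oc,
        nrow(cases), nrow(agg))
    set_stats <- list()
    prof <- purrr::map(config$lags, function(lg) {
      sets <- assemble_sets(agg, strata, labels, met, lag = lg,
                            holidays = holidays,
                            adjust_pollutants = config$adjust_pollutants,
                            quiet = TRUE)
      sets <- collapse_sets(sets)
      set_stats[[as.character(lg)]] <<- list(
        n_sets = attr(sets, "n_sets"),
        dropped_exposure = attr(sets, "n_dropped_exposure"),
        dropped_met = attr(sets, "n_dropped_met"),
        dropped_singleton = attr(sets, "n_dropped_singleton")
      )
      if (config$write_sets) {
        write_output_csv(
          as_tibble(sets), config$out_dir,
          sprintf("matched_sets_%s_lag%d.csv", oc, lg)
        )
      }
      fit <- tryCatch(fit_clogit(sets), error = function(e) e)
      if (inherits(fit, "error")) {
        return(tibble(
          outcome = oc, lag = lg, or = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, n_sets = attr(sets, "n_sets") %||% 0L,
          converged = FALSE, separation = NA, note = conditionMessage(fit)
        ))
      }
      tibble(
        outcome = oc, lag = lg, or = fit$dust_or[["or"]],
        ci_low = fit$dust_or[["low"]], ci_high = fit$dust_or[["high"]],
        n_sets = fit$n_sets, converged = fit$converged,
        separation = fit$separation_flag, note = NA_character_
      )
    }) |> dplyr::bind_rows()
    counts[[oc]]$sets <- set_stats
    results[[oc]] <- prof
  }
  results <- dplyr::bind_rows(results)
  write_output_csv(results, config$out_dir, "results.csv")

  comparison <- dust_comparison_table(records, labels)
  write_output_csv(comparison, config$out_dir, "comparison_table.csv")
  summary_tbl <- site_summary(labels, dplyr::bind_rows(all_cases),
                              met = met, linkage = linkage)
  write_output_csv(summary_tbl, config$out_dir, "site_summary.csv")

  manifest <- list(
    seed = config$seed, buffer_km = config$buffer_km,
    outcomes = config$outcomes, lags = config$lags,
    adjust_pollutants = config$adjust_pollutants,
    period = as.character(period),
    n_monitor_records = nrow(records),
    n_labelled_days = sum(!is.na(labels$dust)),
    n_dust_days = n_dust,
    n_zips = nrow(zips), n_zips_linked = nrow(linkage),
    n_visits = nrow(visits),
    stage_counts = counts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: artifacts in %s", config$out_dir)
  invisible(list(
    results = results, labels = labels, linkage = linkage,
    comparison_table = comparison, site_summary = summary_tbl,
    manifest = manifest, out_dir = config$out_dir
  ))
}

#' Lag-odds-ratio report table
#'
#' Reshapes a pipeline results table into per-outcome plot data (lag on
#' one axis, OR with CI) and optionally writes it as CSV so rendering is
#' optional.
#'
#' @param results Results tibble from [run_pipeline()] (columns outcome,
#'   lag, or, ci_low, ci_high, ...).
#' @param path Optional CSV path to write.
#' @return The report tibble, classed for [autoplot()].
#' @export
report_lag_table <- function(results, path = NULL) {
  need <- c("outcome", "lag", "or", "ci_low", "ci_high")
  if (!all(need %in% names(results))) {
    abort("`results` must carry outcome, lag, or, ci_low, ci_high columns.")
  }
  out <- results |>
    dplyr::select(dplyr::all_of(need), dplyr::any_of(c("n_sets", "converged"))) |>
    dplyr::arrange(.data$outcome, .data$lag) |>
    dplyr::rename(group = "outcome")
  if (!is.null(path)) readr::write_csv(out, path, na = "")
  class(out) <- c("dustcase_lag_profile", class(out))
  out
}
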