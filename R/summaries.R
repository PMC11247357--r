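# Descriptive tables: the dust vs non-dust composition comparison and
# the per-site summary of dust days, covariates, and visit counts.

# footnote arithmetic shared by the comparison table: difference of
# means and the difference relative to the non-dust mean
comparison_arithmetic <- function(mean_dust, mean_nondust) {
  difference <- mean_dust - mean_nondust
  relative <- ifelse(mean_nondust == 0, NA_real_, difference / mean_nondust)
  tibble(
    difference = difference,
    relative_difference = relative,
    relative_undefined = mean_nondust == 0
  )
}

#' Compare PM mass and composition on dust vs non-dust days
#'
#' For each variable, computes n / mean / SD over labelled site-days in
#' each regime (missing values excluded per variable, so n varies by
#' row), the difference of means, and the difference relative to the
#' non-dust mean. All stored values are unrounded; rounding is a display
#' concern.
#'
#' @param records Monitor record tibble.
#' @param labels Label table (site_id, date, dust); unlabelled site-days
#'   are excluded.
#' @param variables Record columns to summarise.
#' @return Tibble with one row per variable: variable, n_dust, mean_dust,
#'   sd_dust, n_nondust, mean_nondust, sd_nondust, difference,
#'   relative_difference, relative_undefined.
#' @export
dust_comparison_table <- function(records, labels,
                                  variables = c("pm10", "pm_coarse", "pm25",
                                                "Si", "NO3", "SO4", "EC", "OC")) {
  records <- as_tibble(records)
  if (!"pm_coarse" %in% names(records) && "pm_coarse" %in% variables &&
      all(c("pm10", "pm25") %in% names(records))) {
    records$pm_coarse <- records$pm10 - records$pm25
  }
  absent <- setdiff(variables, names(records))
  if (length(absent)) {
    abort(paste0("Variable(s) absent from records: ",
                 paste(absent, collapse = ", "), "."))
  }
  df <- dplyr::inner_join(
    records,
    dplyr::select(as_tibble(labels), "site_id", "date", "dust"),
    by = c("site_id", "date")
  )
  df <- df[!is.na(df$dust), , drop = FALSE]
  one <- function(v) {
    x1 <- df[[v]][df$dust == 1]
    x0 <- df[[v]][df$dust == 0]
    x1 <- x1[!is.na(x1)]
    x0 <- x0[!is.na(x0)]
    m1 <- mean(x1)
    m0 <- mean(x0)
    dplyr::bind_cols(
      tibble(
        variable = v,
        n_dust = length(x1), mean_dust = m1, sd_dust = stats::sd(x1),
        n_nondust = length(x0), mean_nondust = m0, sd_nondust = stats::sd(x0)
      ),
      comparison_arithmetic(m1, m0)
    )
  }
  dplyr::bind_rows(lapply(variables, one))
}

#' Per-site summary of dust days, covariates, and visit counts
#'
#' One row per site: number of dust storm days, daily mean (SD) of each
#' covariate over the site's linked ZIPs, and visit counts per outcome;
#' plus a `Total` row in which every count column is the column sum.
#'
#' @param labels Site-day label table (site_id, date, dust).
#' @param cases Ascertained visits carrying `site_id` and `outcome`
#'   columns (e.g. row-bound outputs of [select_visits()]).
#' @param met Optional ZIP-day covariate table (zip_id, date, covariates).
#' @param linkage Optional [assign_sites()] output, required with `met`.
#' @return Tibble, one row per site plus the total row.
#' @export
site_summary <- function(labels, cases, met = NULL, linkage = NULL) {
  labels <- as_tibble(labels)
  sites <- sort(unique(labels$site_id))
  dust_counts <- labels |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_dust_days = sum(.data$dust == 1, na.rm = TRUE),
                     n_labelled = sum(!is.na(.data$dust)), .groups = "drop")
  out <- tibble(site_id = sites) |>
    dplyr::left_join(dust_counts, by = "site_id")

  if (!is.null(met)) {
    if (is.null(linkage)) abort("`linkage` is required when `met` is given.")
    met_site <- dplyr::inner_join(
      as_tibble(met),
      dplyr::select(as_tibble(linkage), "zip_id", "site_id"),
      by = "zip_id"
    )
    covs <- setdiff(names(met), c("zip_id", "date"))
    stats_tbl <- met_site |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(covs),
        list(mean = ~mean(.x, na.rm = TRUE), sd = ~stats::sd(.x, na.rm = TRUE))
      ), .groups = "drop")
    out <- dplyr::left_join(out, stats_tbl, by = "site_id")
  }

  if (!is.null(cases) && nrow(cases) > 0) {
    counts <- as_tibble(cases) |>
      dplyr::count(.data$site_id, .data$outcome) |>
      tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                         values_fill = 0L)
    out <- dplyr::left_join(out, counts, by = "site_id")
    cnt_cols <- setdiff(names(counts), "site_id")
    out[cnt_cols] <- lapply(out[cnt_cols], function(x) tidyr::replace_na(x, 0L))
  }

  count_cols <- intersect(
    c("n_dust_days", "n_labelled",
      setdiff(names(out), c("site_id", "n_dust_days", "n_labelled",
                            grep("_(mean|sd)$", names(out), value = TRUE)))),
    names(out)
  )
  total <- tibble(site_id = "Total")
  for (cc in count_cols) total[[cc]] <- sum(out[[cc]], na.rm = TRUE)
  dplyr::bind_rows(out, total)
}
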