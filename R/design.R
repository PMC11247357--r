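# Customized time-stratified case-crossover design. Because exposure is
# only measured every 3rd or 6th day, referents cannot be matched on day
# of week; instead each stratum holds 4 calendar days at 6-day intervals
# inside a 24-day block, so referent days share the case day's position
# in the monitor sampling cycle and fall both before and after cases on
# average.

#' Build the customized case-crossover strata
#'
#' Every day in `[date_start, date_end]` is keyed to exactly one stratum
#' by `(block, phase) = (floor(offset / 24), offset mod 6)` with `offset`
#' the day count since `date_start`. Full 24-day blocks contain 6 strata
#' of 4 days each, spaced 6 days apart (span 18 days, inside a 24-day
#' window); the terminal partial block may hold smaller strata.
#'
#' @param date_start,date_end Analysis period (the stratum anchor is
#'   `date_start`, so state-specific periods get state-specific strata).
#' @return Tibble: date, offset, block, phase, stratum_id; attribute
#'   `date_start`. Class `cco_strata`.
#' @export
#' @examples
#' s <- build_strata("2010-01-01", "2010-01-24")
#' table(table(s$stratum_id)) # six strata of four days
build_strata <- function(date_start, date_end) {
  date_start <- as_iso_date(date_start, "date_start")
  date_end <- as_iso_date(date_end, "date_end")
  if (date_end < date_start) abort("`date_end` must not precede `date_start`.")
  dates <- seq(date_start, date_end, by = 1)
  offset <- as.integer(dates - date_start)
  block <- offset %/% 24L
  phase <- offset %% 6L
  out <- tibble(
    date = dates, offset = offset, block = block, phase = phase,
    stratum_id = sprintf("B%04d.P%d", block, phase)
  )
  attr(out, "date_start") <- date_start
  class(out) <- c("cco_strata", class(out))
  out
}

# day-of-week indicator block, Sunday as reference
dow_indicators <- function(dates) {
  wd <- as.POSIXlt(dates)$wday # 0 = Sunday
  out <- lapply(1:6, function(k) as.numeric(wd == k))
  names(out) <- paste0("dow_", c("mon", "tue", "wed", "thu", "fri", "sat"))
  as_tibble(out)
}

#' Build the model covariates for member days
#'
#' Day-of-week and holiday indicators are evaluated at the member date
#' itself (they adjust visit-day behaviour), while meteorology — linear,
#' squared, and cubic maximum temperature and dew point — and optional
#' co-pollutants are taken at `member_date - lag`, the same lag as the
#' dust indicator.
#'
#' @param dates Member dates.
#' @param zip_id ZIP of each member (for the meteorology lookup).
#' @param lag Integer lag in 0..5.
#' @param met ZIP-day meteorology table (zip_id, date, tmax, dewpoint,
#'   and pm25/no2/o3 when adjusting for co-pollutants).
#' @param holidays Holiday dates (default: fixed-date federal holidays
#'   spanning `dates`).
#' @param adjust_pollutants Add linear PM2.5, NO2, O3 terms.
#' @param lag_dow Evaluate day-of-week/holiday at the lagged date instead
#'   of the member date.
#' @return Tibble of covariate columns, one row per member; rows with no
#'   meteorology at the lagged date contain `NA`.
#' @export
build_covariates <- function(dates, zip_id, lag, met, holidays = NULL,
                             adjust_pollutants = FALSE, lag_dow = FALSE) {
  if (!all(lag %in% 0:5)) abort("`lag` must lie in 0..5.")
  dates <- as_iso_date(dates, "dates")
  if (is.null(holidays)) {
    holidays <- if (length(dates) == 0) as.Date(character()) else {
      yrs <- unique(as.integer(format(dates, "%Y")))
      us_federal_holidays(seq(min(yrs) - 1, max(yrs)))
    }
  }
  cal_dates <- if (lag_dow) dates - lag else dates
  out <- dow_indicators(cal_dates)
  out$holiday <- as.numeric(cal_dates %in% holidays)
  idx <- match(paste(zip_id, dates - lag), paste(met$zip_id, met$date))
  tm <- met$tmax[idx]
  dp <- met$dewpoint[idx]
  out$tmax1 <- tm; out$tmax2 <- tm^2; out$tmax3 <- tm^3
  out$dew1 <- dp; out$dew2 <- dp^2; out$dew3 <- dp^3
  if (adjust_pollutants) {
    need <- c("pm25", "no2", "o3")
    if (!all(need %in% names(met))) {
      abort("`met` lacks pm25/no2/o3 columns required for co-pollutant adjustment.")
    }
    out$pm25 <- met$pm25[idx]
    out$no2 <- met$no2[idx]
    out$o3 <- met$o3[idx]
  }
  out
}

#' Assemble matched case-referent sets with lagged exposure
#'
#' Each case contributes one set over the dates of its stratum: the case
#' day plus up to 3 referent days. The dust indicator at the analysis lag
#' and the model covariates are attached to every member. Sets in which
#' any member's lagged dust indicator is missing are dropped entirely, as
#' are sets with missing lagged meteorology and singleton strata (a set
#' needs at least one referent).
#'
#' @param cases Tibble: visit_id, admission_date, zip_id, site_id,
#'   optional weight (visit multiplicity, default 1).
#' @param strata Output of [build_strata()] covering all case dates.
#' @param labels Site-day label table (site_id, date, dust).
#' @param met ZIP-day meteorology table.
#' @param lag Analysis lag in 0..5.
#' @inheritParams build_covariates
#' @param quiet Suppress the drop-count message.
#' @return Member-level tibble of class `matched_sets`: set_id, zip_id,
#'   case_date, member_date, is_case, exposure, weight, covariates.
#'   Attributes `lag`, `n_cases`, `n_sets`, `n_dropped_exposure`,
#'   `n_dropped_met`, `n_dropped_singleton`.
#' @export
assemble_sets <- function(cases, strata, labels, met, lag = 0L,
                          holidays = NULL, adjust_pollutants = FALSE,
                          lag_dow = FALSE, quiet = FALSE) {
  if (!all(lag %in% 0:5)) abort("`lag` must lie in 0..5.")
  cases <- as_tibble(cases)
  cases$admission_date <- as_iso_date(cases$admission_date, "admission_date")
  if (!"weight" %in% names(cases)) cases$weight <- 1
  outside <- !cases$admission_date %in% strata$date
  if (any(outside)) {
    abort(paste0(sum(outside), " case date(s) outside the strata range, e.g. ",
                 format(cases$admission_date[outside][1]), "."))
  }
  skey <- strata$stratum_id[match(cases$admission_date, strata$date)]
  members_of <- split(strata$date, strata$stratum_id)
  sizes <- lengths(members_of)[skey]
  singleton <- sizes < 2L
  n_singleton <- sum(cases$weight[singleton])
  cases <- cases[!singleton, , drop = FALSE]
  skey <- skey[!singleton]

  mem <- tibble(
    set_id = rep(cases$visit_id, lengths(members_of)[skey]),
    zip_id = rep(cases$zip_id, lengths(members_of)[skey]),
    site_id = rep(cases$site_id, lengths(members_of)[skey]),
    case_date = rep(cases$admission_date, lengths(members_of)[skey]),
    weight = rep(cases$weight, lengths(members_of)[skey]),
    member_date = as.Date(unlist(members_of[skey], use.names = FALSE))
  )
  mem$is_case <- mem$member_date == mem$case_date

  lab <- setNames(labels$dust, paste(labels$site_id, labels$date))
  mem$exposure <- as.numeric(lab[paste(mem$site_id, mem$member_date - lag)])

  drop_expo <- unique(mem$set_id[is.na(mem$exposure)])
  mem <- mem[!mem$set_id %in% drop_expo, , drop = FALSE]

  cov <- build_covariates(mem$member_date, mem$zip_id, lag, met,
                          holidays = holidays,
                          adjust_pollutants = adjust_pollutants,
                          lag_dow = lag_dow)
  miss_met <- rowSums(is.na(cov)) > 0
  drop_met <- unique(mem$set_id[miss_met])
  keep <- !mem$set_id %in% drop_met
  mem <- dplyr::bind_cols(mem, cov)[keep, , drop = FALSE]
  mem <- dplyr::arrange(mem, .data$set_id, .data$member_date)
  mem <- dplyr::select(mem, -"site_id")

  if (!quiet) {
    inform(sprintf(
      "lag %d: %d sets retained; dropped %d (missing exposure), %d (missing meteorology), %s singleton-stratum case(s).",
      lag, length(unique(mem$set_id)), length(drop_expo), length(drop_met),
      format(n_singleton)
    ))
  }
  structure(
    mem,
    lag = as.integer(lag),
    n_cases = nrow(cases) + sum(singleton),
    n_sets = length(unique(mem$set_id)),
    n_dropped_exposure = length(drop_expo),
    n_dropped_met = length(drop_met),
    n_dropped_singleton = n_singleton,
    class = c("matched_sets", class(mem))
  )
}

#' Collapse identical matched sets into weighted sets
#'
#' Sets identical in member dates, exposure vector, covariate matrix and
#' case position merge into one set whose weight is the sum of the merged
#' weights. Total weight is conserved and the conditional likelihood is
#' unchanged (it depends on sets only through those quantities).
#'
#' @param sets A `matched_sets` tibble from [assemble_sets()].
#' @return A `matched_sets` tibble with one representative per identity
#'   class and summed weights.
#' @export
collapse_sets <- function(sets) {
  if (nrow(sets) == 0) return(sets)
  sets <- dplyr::arrange(sets, .data$set_id, .data$member_date)
  sig_cols <- setdiff(names(sets), c("set_id", "zip_id", "weight"))
  row_sig <- do.call(paste, c(unclass(sets)[sig_cols], sep = "\r"))
  set_f <- factor(sets$set_id, levels = unique(sets$set_id))
  set_sig <- tapply(row_sig, set_f, paste, collapse = "\n")
  per_set <- tibble(
    set_id = levels(set_f),
    sig = as.character(set_sig[levels(set_f)]),
    weight = sets$weight[!duplicated(sets$set_id)]
  )
  agg <- per_set |>
    dplyr::group_by(.data$sig) |>
    dplyr::summarise(
      rep_set = dplyr::first(.data$set_id),
      weight = sum(.data$weight), .groups = "drop"
    )
  out <- sets[sets$set_id %in% agg$rep_set, , drop = FALSE]
  out$weight <- agg$weight[match(out$set_id, agg$rep_set)]
  for (a in c("lag", "n_cases", "n_dropped_exposure", "n_dropped_met",
              "n_dropped_singleton")) {
    attr(out, a) <- attr(sets, a)
  }
  attr(out, "n_sets") <- nrow(agg)
  out
}
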