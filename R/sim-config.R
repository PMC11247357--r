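#' Fixed-date US federal holidays
#'
#' Returns the fixed-date federal holidays (New Year's Day, Independence
#' Day, Veterans Day, Christmas Day) for a span of years. Floating-date
#' holidays are omitted; supply your own date vector anywhere a holiday
#' calendar is accepted if you need them.
#'
#' @param years Integer vector of calendar years.
#' @return A `Date` vector, sorted.
#' @export
#' @examples
#' us_federal_holidays(2015:2016)
us_federal_holidays <- function(years) {
  stopifnot(is.numeric(years), all(years == floor(years)))
  md <- c("01-01", "07-04", "11-11", "12-25")
  sort(as.Date(paste0(rep(years, each = length(md)), "-", md)))
}

# default lognormal composition parameters (medians in ug/m3 except
# pm25_frac, which is the PM2.5/PM10 mass fraction; gsd = geometric SD).
# Medians track the dust vs non-dust means of the speciated-network
# comparison table; dust-day spreads are kept tight so the default
# configuration is cleanly separable by the five-criteria classifier.
default_composition_params <- function() {
  tibble::tribble(
    ~variable,   ~dust_median, ~dust_gsd, ~nondust_median, ~nondust_gsd,
    "pm10",      59,           1.15,      8.5,             1.7,
    "pm25_frac", 0.21,         1.15,      0.42,            1.3,
    "Si",        2.0,          1.25,      0.19,            1.8,
    "Ca",        0.60,         1.25,      0.06,            1.8,
    "K",         0.30,         1.25,      0.05,            1.8,
    "Fe",        0.60,         1.25,      0.05,            1.8,
    "Ti",        0.08,         1.25,      0.005,           1.8,
    "As",        0.001,        1.3,       0.002,           1.8,
    "Zn",        0.002,        1.3,       0.010,           1.8,
    "Cu",        0.0008,       1.3,       0.008,           1.8,
    "Pb",        0.0005,       1.3,       0.005,           1.8,
    "SO4",       0.85,         1.3,       0.62,            1.8,
    "NO3",       0.32,         1.3,       0.36,            1.9,
    "OC",        0.65,         1.3,       0.61,            1.8,
    "EC",        0.036,        1.3,       0.12,            1.8
  )
}

default_met_params <- function() {
  list(
    tmax     = list(mean = 22, amplitude = 12, sd = 3, peak_doy = 182),
    dewpoint = list(mean = 0,  amplitude = 8,  sd = 3, peak_doy = 182),
    pm25     = list(mean = 3,  amplitude = 1,  sd = 1, peak_doy = 182),
    no2      = list(mean = 12, amplitude = 4,  sd = 3, peak_doy = 15),
    o3       = list(mean = 50, amplitude = 8,  sd = 5, peak_doy = 182)
  )
}

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data streams: the monitor sampling
#' schedule, dust-day frequency and composition distributions, the spatial
#' layout of monitors and ZIP units, visit-generating rates, and the
#' planted exposure effect used for recovery testing.
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param date_start,date_end Study period (ISO dates or `Date`).
#' @param n_sites Number of monitoring sites.
#' @param schedule_days Per-site sampling interval, 3 or 6 (recycled to
#'   `n_sites`).
#' @param p_dust Probability a sampled site-day is a dust day. The default
#'   0.05 is deliberately higher than typical network frequencies so that
#'   desk-scale simulations contain enough events to inform the fit.
#' @param composition_params Data frame with columns `variable`,
#'   `dust_median`, `dust_gsd`, `nondust_median`, `nondust_gsd` giving the
#'   per-regime lognormal parameters for PM10, the PM2.5/PM10 fraction and
#'   each species. Defaults are separable by the default classifier.
#' @param n_zips_per_site ZIP units generated around each site, at ring
#'   distances spanning both sides of a 50 km buffer.
#' @param zip_radius_km Effective ZIP radius (disc model), km.
#' @param baseline_rate Expected visits per ZIP-day before covariate and
#'   exposure effects.
#' @param beta_true Planted log odds ratio of a visit on a day whose
#'   lag-`lag_true` site-day is a dust day.
#' @param lag_true Integer lag in 0..5 at which the effect is planted.
#' @param dow_effects Seven log-rate offsets, Sunday first.
#' @param holiday_effect Log-rate offset on holidays.
#' @param holidays Date vector; defaults to fixed-date federal holidays
#'   over the study years.
#' @param season_amplitude Amplitude of a smooth annual log-rate sinusoid
#'   (peak mid-January, emulating winter respiratory load).
#' @param met_params Named list of `list(mean, amplitude, sd, peak_doy)`
#'   for `tmax`, `dewpoint`, `pm25`, `no2`, `o3`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, date_start = "2010-01-01", date_end = "2010-03-31")
sim_config <- function(seed = 1L,
                       date_start = "2005-01-01",
                       date_end = "2010-12-31",
                       n_sites = 2L,
                       schedule_days = 3L,
                       p_dust = 0.05,
                       composition_params = default_composition_params(),
                       n_zips_per_site = 8L,
                       zip_radius_km = 5,
                       baseline_rate = 0.5,
                       beta_true = log(1.5),
                       lag_true = 2L,
                       dow_effects = c(0.10, 0, -0.02, -0.02, 0, 0.02, 0.08),
                       holiday_effect = -0.20,
                       holidays = NULL,
                       season_amplitude = 0.15,
                       met_params = default_met_params()) {
  date_start <- as_iso_date(date_start, "date_start")
  date_end <- as_iso_date(date_end, "date_end")
  if (date_end < date_start) abort("`date_end` must not precede `date_start`.")
  if (!all(schedule_days %in% c(3L, 6L))) abort("`schedule_days` must be 3 or 6.")
  if (p_dust < 0 || p_dust > 1) abort("`p_dust` must lie in [0, 1].")
  if (baseline_rate <= 0) abort("`baseline_rate` must be positive.")
  if (!lag_true %in% 0:5) abort("`lag_true` must be an integer in 0..5.")
  if (length(dow_effects) != 7) abort("`dow_effects` must have length 7 (Sunday first).")
  req <- c("variable", "dust_median", "dust_gsd", "nondust_median", "nondust_gsd")
  if (!all(req %in% names(composition_params))) {
    abort("`composition_params` must have columns variable, dust_median, dust_gsd, nondust_median, nondust_gsd.")
  }
  disp <- c(composition_params$dust_gsd, composition_params$nondust_gsd)
  if (any(disp <= 0)) abort("All geometric SDs must be > 0.")
  if (is.null(holidays)) {
    yrs <- seq(as.integer(format(date_start, "%Y")), as.integer(format(date_end, "%Y")))
    holidays <- us_federal_holidays(yrs)
  }
  structure(
    list(
      seed = as.integer(seed), date_start = date_start, date_end = date_end,
      n_sites = as.integer(n_sites),
      schedule_days = rep_len(as.integer(schedule_days), n_sites),
      p_dust = p_dust, composition_params = as_tibble(composition_params),
      n_zips_per_site = as.integer(n_zips_per_site), zip_radius_km = zip_radius_km,
      baseline_rate = baseline_rate, beta_true = beta_true,
      lag_true = as.integer(lag_true), dow_effects = dow_effects,
      holiday_effect = holiday_effect, holidays = as.Date(holidays),
      season_amplitude = season_amplitude, met_params = met_params
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  period   :", format(x$date_start), "to", format(x$date_end), "\n")
  cat("  sites    :", x$n_sites, "(schedule", paste(x$schedule_days, collapse = "/"), "d)\n")
  cat("  p_dust   :", x$p_dust, "\n")
  cat("  zips/site:", x$n_zips_per_site, " baseline rate:", x$baseline_rate, "\n")
  cat("  planted  : beta =", signif(x$beta_true, 4), "at lag", x$lag_true, "\n")
  invisible(x)
}
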