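# Synthetic input streams: monitor series with planted dust days,
# site/ZIP geography, ZIP-day meteorology and co-pollutants, and
# patient-level visit records with a planted lag-specific exposure effect.
# Every generator derives its RNG stream from cfg$seed plus a fixed
# per-stage offset, so streams are reproducible independently and jointly.

seed_offset <- c(monitor = 101L, geography = 102L, met = 103L, visits = 104L)

rlnorm_med <- function(n, median, gsd) {
  stats::rlnorm(n, meanlog = log(median), sdlog = log(gsd))
}

#' Generate a speciated monitor series with known dust-day truth
#'
#' Produces one record per scheduled site-day (start date, then every
#' `schedule_days`). Each sampled day is a dust day with probability
#' `p_dust`; dust and non-dust records are drawn from the per-regime
#' lognormal composition distributions in `cfg$composition_params`.
#' PM2.5 is generated as PM10 times a lognormal fraction (capped at 0.99)
#' so the fine/coarse split is coherent; the coarse fraction is their
#' difference.
#'
#' @param cfg A [sim_config()].
#' @return A list with `records` (tibble: site_id, date, pm10, pm25,
#'   pm_coarse, one column per species) and `truth` (class `sim_truth`:
#'   `labels` tibble with site_id/date/dust, plus `beta_true`, `lag_true`).
#' @export
sim_monitor_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pars <- cfg$composition_params
  withr::with_seed(cfg$seed + seed_offset[["monitor"]], {
    per_site <- purrr::map(seq_len(cfg$n_sites), function(i) {
      dates <- seq(cfg$date_start, cfg$date_end, by = cfg$schedule_days[i])
      n <- length(dates)
      dust <- rbinom(n, 1L, cfg$p_dust)
      draws <- purrr::map(seq_len(nrow(pars)), function(j) {
        med <- ifelse(dust == 1L, pars$dust_median[j], pars$nondust_median[j])
        gsd <- ifelse(dust == 1L, pars$dust_gsd[j], pars$nondust_gsd[j])
        rlnorm_med(n, med, gsd)
      })
      names(draws) <- pars$variable
      rec <- tibble(site_id = site_label(i), date = dates, dust = dust)
      dplyr::bind_cols(rec, as_tibble(draws))
    })
    all <- dplyr::bind_rows(per_site)
  })
  all$pm25 <- all$pm10 * pmin(all$pm25_frac, 0.99)
  all$pm_coarse <- all$pm10 - all$pm25
  species <- setdiff(pars$variable, c("pm10", "pm25_frac"))
  records <- dplyr::select(
    all, "site_id", "date", "pm10", "pm25", "pm_coarse",
    dplyr::all_of(species)
  )
  truth <- structure(
    list(
      labels = dplyr::select(all, "site_id", "date", "dust"),
      beta_true = cfg$beta_true, lag_true = cfg$lag_true
    ),
    class = "sim_truth"
  )
  list(records = records, truth = truth)
}

site_label <- function(i) sprintf("SITE%02d", i)

#' Generate monitor sites and surrounding ZIP units
#'
#' Sites are placed on a widely separated longitude line; each site is
#' ringed by `n_zips_per_site` ZIP discs whose centroid distances are
#' evenly spread from 5 km to 75 km, so the generated layout always
#' exercises both sides of a 50 km buffer (and of a 15 km one).
#'
#' @param cfg A [sim_config()].
#' @return List with `sites` (site_id, latitude, longitude) and
#'   `zip_units` (zip_id, latitude, longitude, radius_km, origin_site_id).
#' @export
sim_geography <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_sites >= 1)
  sites <- tibble(
    site_id = site_label(seq_len(cfg$n_sites)),
    latitude = 35,
    longitude = -118 + 4 * (seq_len(cfg$n_sites) - 1)
  )
  nz <- cfg$n_zips_per_site
  if (nz == 0) {
    zips <- tibble(
      zip_id = character(), latitude = numeric(), longitude = numeric(),
      radius_km = numeric(), origin_site_id = character()
    )
    return(list(sites = sites, zip_units = zips))
  }
  km_per_deg <- pi * 6371 / 180
  withr::with_seed(cfg$seed + seed_offset[["geography"]], {
    zips <- purrr::map(seq_len(cfg$n_sites), function(i) {
      d <- if (nz == 1) 25 else seq(5, 75, length.out = nz)
      ang <- stats::runif(nz, 0, 2 * pi)
      tibble(
        zip_id = sprintf("Z%02d%02d", i, seq_len(nz)),
        latitude = sites$latitude[i] + d * cos(ang) / km_per_deg,
        longitude = sites$longitude[i] +
          d * sin(ang) / (km_per_deg * cos(sites$latitude[i] * pi / 180)),
        radius_km = cfg$zip_radius_km,
        origin_site_id = sites$site_id[i]
      )
    })
    zips <- dplyr::bind_rows(zips)
  })
  list(sites = sites, zip_units = zips)
}

seasonal_series <- function(doy, p, n_noise) {
  p$mean + p$amplitude * cos(2 * pi * (doy - p$peak_doy) / 365.25) +
    rnorm(n_noise, 0, p$sd)
}

#' Generate daily ZIP-level meteorology and co-pollutants
#'
#' Every ZIP-day gets maximum temperature, mean dew point, and daily
#' PM2.5 / NO2 / O3 as a seasonal sinusoid plus Gaussian noise, per
#' `cfg$met_params`. Pollutant series are floored at zero. No missing
#' values are produced.
#'
#' @param cfg A [sim_config()].
#' @param zip_units ZIP table from [sim_geography()].
#' @return Tibble: zip_id, date, tmax, dewpoint, pm25, no2, o3.
#' @export
sim_meteorology <- function(cfg, zip_units) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(zip_units) == 0) abort("`zip_units` must be non-empty.")
  dates <- seq(cfg$date_start, cfg$date_end, by = 1)
  grid <- tidyr::expand_grid(zip_id = zip_units$zip_id, date = dates)
  doy <- as.integer(format(grid$date, "%j"))
  n <- nrow(grid)
  mp <- cfg$met_params
  withr::with_seed(cfg$seed + seed_offset[["met"]], {
    grid$tmax <- seasonal_series(doy, mp$tmax, n)
    grid$dewpoint <- seasonal_series(doy, mp$dewpoint, n)
    grid$pm25 <- pmax(0, seasonal_series(doy, mp$pm25, n))
    grid$no2 <- pmax(0, seasonal_series(doy, mp$no2, n))
    grid$o3 <- pmax(0, seasonal_series(doy, mp$o3, n))
  })
  grid
}

# diagnosis-code pool used to dress visit counts as billing records;
# one exemplar ICD-9 and ICD-10 code per condition, era chosen by date
visit_code_pool <- function() {
  tibble::tribble(
    ~condition,   ~icd9,   ~icd10,  ~prob,
    "asthma",     "49302", "J4521", 0.10,
    "copd",       "4918",  "J441",  0.06,
    "bronchitis", "4660",  "J209",  0.08,
    "pneumonia",  "486",   "J189",  0.08,
    "uri",        "465",   "J069",  0.10,
    "ihd",        "41071", "I219",  0.07,
    "dysrhythmia","42731", "I4891", 0.07,
    "chf",        "4280",  "I509",  0.06,
    "hypertension","4019", "I10",   0.12,
    "injury",     "95901", "S0990", 0.26
  )
}

#' Generate patient-level ED visit records with a planted dust effect
#'
#' Visit counts per ZIP-day are Poisson with log-mean
#' `log(baseline_rate) + beta_true * dust(site, date - lag_true) +
#' dow + holiday + season`, where `dust()` is the generating site's
#' planted label (an unsampled lag day contributes 0). Counts are then
#' exploded to one row per visit with never-reused visit identifiers and
#' diagnosis codes drawn from a configured condition pool, coded in the
#' ICD era implied by the admission date (ICD-9 before 2015-10-01,
#' ICD-10 from that date on).
#'
#' @param cfg A [sim_config()].
#' @param truth `sim_truth` from [sim_monitor_series()].
#' @param zip_units ZIP table from [sim_geography()] (needs
#'   `origin_site_id`).
#' @param met Unused by the rate model (visit rates do not depend on
#'   weather in the generator); accepted for interface symmetry.
#' @return Tibble: visit_id, admission_date, zip_id, dx1, dx2 (dx2 may
#'   be `NA`).
#' @export
sim_visits <- function(cfg, truth, zip_units, met = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  if (cfg$baseline_rate <= 0) abort("`baseline_rate` must be > 0.")
  if (!"origin_site_id" %in% names(zip_units)) {
    abort("`zip_units` must carry `origin_site_id` linking each ZIP to its generating site.")
  }
  dates <- seq(cfg$date_start, cfg$date_end, by = 1)
  grid <- tidyr::expand_grid(
    zip_id = zip_units$zip_id, date = dates
  )
  grid <- dplyr::left_join(
    grid, dplyr::select(zip_units, "zip_id", "origin_site_id"),
    by = "zip_id"
  )
  # planted exposure: site label at date - lag_true, 0 when unsampled
  key <- paste(truth$labels$site_id, truth$labels$date)
  lab <- setNames(truth$labels$dust, key)
  expo <- lab[paste(grid$origin_site_id, grid$date - truth$lag_true)]
  expo[is.na(expo)] <- 0L
  doy <- as.integer(format(grid$date, "%j"))
  wday <- as.POSIXlt(grid$date)$wday + 1L # 1 = Sunday
  log_mu <- log(cfg$baseline_rate) +
    truth$beta_true * expo +
    cfg$dow_effects[wday] +
    cfg$holiday_effect * (grid$date %in% cfg$holidays) +
    cfg$season_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  pool <- visit_code_pool()
  withr::with_seed(cfg$seed + seed_offset[["visits"]], {
    n_vis <- rpois(nrow(grid), exp(log_mu))
    idx <- rep.int(seq_len(nrow(grid)), n_vis)
    total <- length(idx)
    cond <- sample.int(nrow(pool), total, replace = TRUE, prob = pool$prob)
    has_dx2 <- stats::runif(total) < 0.3
    cond2 <- sample.int(nrow(pool), total, replace = TRUE, prob = pool$prob)
  })
  adm <- grid$date[idx]
  icd10_era <- adm >= as.Date("2015-10-01")
  visits <- tibble(
    visit_id = sprintf("V%08d", seq_len(total)),
    admission_date = adm,
    zip_id = grid$zip_id[idx],
    dx1 = ifelse(icd10_era, pool$icd10[cond], pool$icd9[cond]),
    dx2 = ifelse(has_dx2, ifelse(icd10_era, pool$icd10[cond2], pool$icd9[cond2]),
                 NA_character_)
  )
  visits
}

#' Generate a complete synthetic study
#'
#' Runs all four generators and returns every stream plus ground truth.
#'
#' @param cfg A [sim_config()].
#' @return List: records, truth, sites, zip_units, met, visits.
#' @export
#' @examples
#' study <- sim_study(sim_config(seed = 7, date_end = "2005-06-30"))
#' names(study)
sim_study <- function(cfg) {
  mon <- sim_monitor_series(cfg)
  geo <- sim_geography(cfg)
  met <- sim_meteorology(cfg, geo$zip_units)
  visits <- sim_visits(cfg, mon$truth, geo$zip_units, met)
  list(
    records = mon$records, truth = mon$truth,
    sites = geo$sites, zip_units = geo$zip_units,
    met = met, visits = visits
  )
}
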