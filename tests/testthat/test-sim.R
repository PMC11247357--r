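test_that("monitor series respects the sampling schedule and no-event limit", {
  cfg <- sim_config(seed = 1, date_start = "2010-01-01", date_end = "2010-01-30",
                    n_sites = 1, schedule_days = 3, p_dust = 0)
  mon <- sim_monitor_series(cfg)
  expect_equal(nrow(mon$records), 10)
  expect_true(all(mon$truth$labels$dust == 0))
  expect_true(all(as.integer(mon$records$date - cfg$date_start) %% 3 == 0))

  cfg6 <- sim_config(seed = 1, date_start = "2010-01-01", date_end = "2010-03-01",
                     n_sites = 1, schedule_days = 6)
  mon6 <- sim_monitor_series(cfg6)
  expect_equal(nrow(mon6$records), 10) # one per 6th day over 60 days
  expect_equal(diff(mon6$records$date), rep(6, 9), ignore_attr = TRUE)
})

test_that("labels exist exactly for sampled site-days", {
  cfg <- sim_config(seed = 5, date_start = "2010-01-01", date_end = "2010-06-30",
                    n_sites = 3, schedule_days = c(3, 6, 3))
  mon <- sim_monitor_series(cfg)
  expect_identical(
    paste(mon$records$site_id, mon$records$date),
    paste(mon$truth$labels$site_id, mon$truth$labels$date)
  )
})

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 99, date_start = "2010-01-01", date_end = "2010-12-31")
  a <- sim_study(cfg)
  b <- sim_study(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$zip_units, b$zip_units)
  expect_identical(a$met, b$met)
  expect_identical(a$visits, b$visits)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(date_start = "2010-01-02", date_end = "2010-01-01"),
               "date_end")
  expect_error(sim_config(schedule_days = 4), "3 or 6")
  expect_error(sim_config(p_dust = 1.2), "p_dust")
  expect_error(sim_config(baseline_rate = 0), "baseline_rate")
  expect_error(sim_config(lag_true = 7), "lag_true")
})

test_that("dust and non-dust composition regimes are separated as configured", {
  # ~10,800 sampled site-days
  cfg <- sim_config(seed = 7, date_start = "2005-01-01", date_end = "2013-11-15",
                    n_sites = 10, p_dust = 0.5)
  mon <- sim_monitor_series(cfg)
  df <- dplyr::inner_join(mon$records, mon$truth$labels,
                          by = c("site_id", "date"))
  expect_gt(nrow(df), 10000)
  m_dust <- mean(df$pm10[df$dust == 1])
  m_non <- mean(df$pm10[df$dust == 0])
  expect_gt(m_dust, m_non)
  # lognormal mean = median * exp(log(gsd)^2 / 2); check within MC error
  expect_equal(m_dust, 59 * exp(log(1.15)^2 / 2), tolerance = 0.02)
  expect_equal(m_non, 8.5 * exp(log(1.7)^2 / 2), tolerance = 0.05)
  expect_gt(mean(df$Si[df$dust == 1]), mean(df$Si[df$dust == 0]))
  # coarse-dominated on dust days: lower fine/total ratio
  expect_lt(mean(df$pm25[df$dust == 1] / df$pm10[df$dust == 1]),
            mean(df$pm25[df$dust == 0] / df$pm10[df$dust == 0]))
})

test_that("geography spans both sides of the 50 km buffer and is reproducible", {
  cfg <- sim_config(seed = 3, n_sites = 2, n_zips_per_site = 8)
  g1 <- sim_geography(cfg)
  g2 <- sim_geography(cfg)
  expect_identical(g1, g2)
  d <- zip_site_distance_km(
    g1$zip_units$latitude, g1$zip_units$longitude, g1$zip_units$radius_km,
    g1$sites$latitude[match(g1$zip_units$origin_site_id, g1$sites$site_id)],
    g1$sites$longitude[match(g1$zip_units$origin_site_id, g1$sites$site_id)]
  )
  for (s in g1$sites$site_id) {
    ds <- d[g1$zip_units$origin_site_id == s]
    expect_true(any(ds > 50))
    expect_true(any(ds <= 50))
  }
  cfg0 <- sim_config(seed = 3, n_zips_per_site = 0)
  expect_equal(nrow(sim_geography(cfg0)$zip_units), 0)
})

test_that("meteorology follows the configured sinusoid", {
  mp <- list(
    tmax = list(mean = 20, amplitude = 10, sd = 0, peak_doy = 182),
    dewpoint = list(mean = 5, amplitude = 0, sd = 0, peak_doy = 182),
    pm25 = list(mean = 3, amplitude = 1, sd = 0, peak_doy = 182),
    no2 = list(mean = 12, amplitude = 4, sd = 0, peak_doy = 15),
    o3 = list(mean = 50, amplitude = 8, sd = 0, peak_doy = 182)
  )
  cfg <- sim_config(seed = 2, date_start = "2010-01-01", date_end = "2010-12-31",
                    n_sites = 1, n_zips_per_site = 2, met_params = mp)
  geo <- sim_geography(cfg)
  met <- sim_meteorology(cfg, geo$zip_units)
  doy <- as.integer(format(met$date, "%j"))
  expect_equal(met$tmax, 20 + 10 * cos(2 * pi * (doy - 182) / 365.25))
  expect_equal(met$dewpoint, rep(5, nrow(met))) # zero amplitude, zero noise
  expect_false(anyNA(met))

  cfg2 <- sim_config(seed = 2, date_start = "2010-01-01", date_end = "2010-12-31",
                     n_sites = 1, n_zips_per_site = 4)
  met2 <- sim_meteorology(cfg2, sim_geography(cfg2)$zip_units)
  # annual mean of the sinusoid is ~the configured mean; noise SE is tiny at n=1460
  se <- 3 / sqrt(nrow(met2))
  expect_lt(abs(mean(met2$tmax) - 22), 3 * se + 0.05)
  expect_error(sim_meteorology(cfg2, data.frame()), "non-empty")
})

test_that("visit counts are Poisson with the configured log-linear mean", {
  flat <- sim_config(
    seed = 31, date_start = "2010-01-01", date_end = "2010-01-25",
    n_sites = 1, n_zips_per_site = 4, p_dust = 0, baseline_rate = 2,
    beta_true = 0, dow_effects = rep(0, 7), holiday_effect = 0,
    season_amplitude = 0
  )
  st <- sim_study(flat) # 4 zips x 25 days = 100 zip-days at lambda 2
  expect_lt(abs(nrow(st$visits) - 200), 4 * sqrt(200))

  tiny <- sim_config(seed = 31, date_start = "2010-01-01",
                     date_end = "2010-01-25", n_sites = 1,
                     n_zips_per_site = 4, baseline_rate = 1e-6,
                     dow_effects = rep(0, 7), season_amplitude = 0)
  expect_lt(nrow(sim_study(tiny)$visits), 3)
})

test_that("a planted log(2) effect doubles the exposed visit rate", {
  cfg <- sim_config(
    seed = 17, date_start = "2005-01-01", date_end = "2012-12-31",
    n_sites = 2, n_zips_per_site = 4, p_dust = 0.5, baseline_rate = 1,
    beta_true = log(2), lag_true = 0, dow_effects = rep(0, 7),
    holiday_effect = 0, season_amplitude = 0
  )
  st <- sim_study(cfg)
  lab <- st$truth$labels
  counts <- dplyr::count(st$visits, .data$zip_id, date = .data$admission_date)
  grid <- tidyr::expand_grid(
    zip_id = st$zip_units$zip_id,
    date = unique(lab$date) # exposure defined only on sampled days at lag 0
  )
  grid$site <- st$zip_units$origin_site_id[match(grid$zip_id, st$zip_units$zip_id)]
  grid$dust <- lab$dust[match(paste(grid$site, grid$date),
                              paste(lab$site_id, lab$date))]
  grid$n <- counts$n[match(paste(grid$zip_id, grid$date),
                           paste(counts$zip_id, counts$date))]
  grid$n[is.na(grid$n)] <- 0L
  ratio <- mean(grid$n[grid$dust == 1]) / mean(grid$n[grid$dust == 0])
  expect_equal(ratio, 2, tolerance = 0.08)
})

test_that("visit identifiers are unique and ICD era follows the admission date", {
  st <- small_study(seed = 8, years = 2)$study
  expect_false(any(duplicated(st$visits$visit_id)))
  era10 <- st$visits$admission_date >= as.Date("2015-10-01")
  expect_true(all(grepl("^[0-9]", st$visits$dx1[!era10])))
  cfg16 <- sim_config(seed = 8, date_start = "2015-09-01",
                      date_end = "2016-01-31", n_sites = 1)
  st16 <- sim_study(cfg16)
  era10 <- st16$visits$admission_date >= as.Date("2015-10-01")
  expect_true(all(grepl("^[A-Z]", st16$visits$dx1[era10])))
  expect_true(all(grepl("^[0-9]", st16$visits$dx1[!era10])))
})
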