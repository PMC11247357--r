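test_that("log-likelihood closed forms hold", {
  # beta = 0: every member equally likely -> -N log 4 for size-4 sets
  sets <- rand_sets(25, seed = 1)
  expect_equal(clogit_loglik(0, sets)$value, -25 * log(4))
  # one set, case exposed, three unexposed referents, beta = log 2:
  # P(case) = 2 / (2 + 1 + 1 + 1)
  one <- tibble::tibble(
    set_id = "s", member_date = as.Date("2010-01-01") + c(0, 6, 12, 18),
    is_case = c(TRUE, FALSE, FALSE, FALSE), exposure = c(1, 0, 0, 0),
    weight = 1
  )
  expect_equal(clogit_loglik(log(2), one)$value, log(2 / 5))
  # concordant set: gradient contribution identically zero
  conc <- one
  conc$exposure <- 1
  for (b in c(-2, 0, 1.3)) {
    expect_equal(clogit_loglik(b, conc)$gradient, 0, ignore_attr = TRUE)
  }
})

test_that("analytic gradient and Hessian match finite differences", {
  sets <- rand_sets(12, seed = 3, n_extra = 2)
  terms <- c("exposure", "x1", "x2")
  withr::with_seed(4, beta <- rnorm(3, 0, 0.5))
  an <- clogit_loglik(beta, sets, terms = terms)
  eps <- 1e-6
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- eps
    num_g <- (clogit_loglik(beta + e, sets, terms = terms)$value -
              clogit_loglik(beta - e, sets, terms = terms)$value) / (2 * eps)
    expect_equal(an$gradient[j], num_g, tolerance = 1e-6, ignore_attr = TRUE)
    num_h <- (clogit_loglik(beta + e, sets, terms = terms)$gradient -
              clogit_loglik(beta - e, sets, terms = terms)$gradient) / (2 * eps)
    expect_equal(an$hessian[, j], num_h, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("the likelihood value agrees with a direct per-set evaluation", {
  sets <- rand_sets(30, seed = 6)
  for (b in c(-1, 0.3, 2)) {
    expect_equal(clogit_loglik(b, sets)$value, brute_loglik_scalar(b, sets))
  }
})

test_that("Newton-Raphson matches an independent 1-D maximizer", {
  sets <- rand_sets(50, seed = 10)
  fit <- fit_clogit(sets)
  opt <- stats::optimize(function(b) brute_loglik_scalar(b, sets),
                         c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(fit$coefficients[["exposure"]], opt$maximum, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("coefficients and SEs match survival::clogit to 1e-6", {
  skip_if_not_installed("survival")
  sets <- rand_sets(200, seed = 20, n_extra = 2)
  fit <- fit_clogit(sets)
  df <- as.data.frame(sets)
  df$case <- as.integer(df$is_case)
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), case) ~ exposure + x1 + x2 +
      survival::strata(set_id),
    data = df, method = "exact"
  )
  expect_equal(unname(fit$coefficients[c("exposure", "x1", "x2")]),
               unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("set-constant covariates are absorbed without moving other terms", {
  sets <- rand_sets(60, seed = 30, n_extra = 1)
  fit0 <- fit_clogit(sets, terms = c("exposure", "x1"))
  # add a covariate constant within every set: aliased, others unchanged
  withr::with_seed(31, zc <- rnorm(length(unique(sets$set_id))))
  sets$z <- zc[match(sets$set_id, unique(sets$set_id))]
  fit1 <- fit_clogit(sets, terms = c("exposure", "x1", "z"))
  expect_true(is.na(fit1$coefficients[["z"]]))
  expect_equal(fit1$coefficients[["exposure"]], fit0$coefficients[["exposure"]],
               tolerance = 1e-8)
  expect_equal(fit1$coefficients[["x1"]], fit0$coefficients[["x1"]],
               tolerance = 1e-8)
  # shifting a covariate by a set-level constant leaves its coefficient fixed
  sets2 <- sets
  sets2$x1 <- sets2$x1 + 10 * sets2$z
  fit2 <- fit_clogit(sets2, terms = c("exposure", "x1"))
  expect_equal(fit2$coefficients[["x1"]], fit0$coefficients[["x1"]],
               tolerance = 1e-8)
  expect_equal(fit2$loglik, fit0$loglik, tolerance = 1e-8)
})

test_that("non-identifiable and separated exposure terms are reported as such", {
  conc <- rand_sets(10, seed = 40)
  conc$exposure <- 1 # concordant everywhere
  expect_error(fit_clogit(conc), "non-identifiable")
  # complete separation: every case exposed, no referent exposed
  sep <- rand_sets(20, seed = 41)
  sep$exposure <- as.numeric(sep$is_case)
  fit <- suppressWarnings(fit_clogit(sep))
  expect_true(fit$separation_flag)
  expect_true(is.na(fit$dust_or[["or"]]))
})

test_that("a within-set permutation null keeps the dust coefficient near zero", {
  fx_sets <- rand_sets(400, seed = 50, n_extra = 1)
  # permute exposure within each set (destroys any case-exposure link)
  withr::with_seed(51, {
    permuted <- fx_sets |>
      dplyr::group_by(.data$set_id) |>
      dplyr::mutate(exposure = sample(.data$exposure)) |>
      dplyr::ungroup()
  })
  fit <- fit_clogit(permuted)
  z <- fit$coefficients[["exposure"]] / sqrt(fit$vcov["exposure", "exposure"])
  expect_lt(abs(z), 3)
})

test_that("weighted sets reproduce exploded-row fits exactly", {
  withr::with_seed(60, w <- sample(1:5, 40, replace = TRUE))
  wsets <- rand_sets(40, seed = 61, n_extra = 1, weight = w)
  exploded <- purrr::map(unique(wsets$set_id), function(s) {
    block <- wsets[wsets$set_id == s, ]
    k <- block$weight[1]
    purrr::map(seq_len(k), function(r) {
      b <- block
      b$set_id <- paste0(s, "_", r)
      b$weight <- 1
      b
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  b0 <- c(0.4, -0.2)
  lw <- clogit_loglik(b0, wsets, terms = c("exposure", "x1"))
  le <- clogit_loglik(b0, exploded, terms = c("exposure", "x1"))
  expect_equal(lw$value, le$value, tolerance = 1e-10)
  expect_equal(lw$gradient, le$gradient, tolerance = 1e-10)
  expect_equal(lw$hessian, le$hessian, tolerance = 1e-10)
  fw <- fit_clogit(wsets)
  fe <- fit_clogit(exploded)
  expect_equal(fw$coefficients, fe$coefficients, tolerance = 1e-10)
  expect_equal(fw$loglik, fe$loglik, tolerance = 1e-10)
})

test_that("tidy and glance expose the fit in broom form", {
  sets <- rand_sets(80, seed = 70, n_extra = 1)
  fit <- fit_clogit(sets)
  td <- tidy(fit)
  expect_equal(td$term, c("exposure", "x1"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  td_or <- tidy(fit, exponentiate = TRUE)
  expect_equal(td_or$estimate[1], fit$dust_or[["or"]])
  gl <- glance(fit)
  expect_equal(gl$n_sets, 80)
  expect_true(gl$converged)
})

test_that("lag profile recovers the planted lag and handles empty input", {
  st <- small_study(seed = 77, years = 3, baseline_rate = 1)$study
  labs <- classify_series(st$records, date_start = min(st$met$date),
                          date_end = max(st$met$date))
  lk <- assign_sites(st$zip_units, st$sites, 50)
  cases <- select_visits(st$visits, "RD", lk, quiet = TRUE)
  agg <- cases |>
    dplyr::count(.data$zip_id, .data$site_id, .data$admission_date,
                 name = "weight") |>
    dplyr::mutate(visit_id = sprintf("c%05d", dplyr::row_number()))
  strata <- build_strata(min(st$met$date), max(st$met$date))
  prof <- lag_profile(agg, strata, labs, st$met, lags = 0:5)
  expect_equal(nrow(prof), 6)
  expect_true(all(prof$ci_low <= prof$or & prof$or <= prof$ci_high, na.rm = TRUE))
  expect_equal(prof$lag[which.max(abs(prof$beta))], 2)
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
  expect_error(lag_profile(agg[0, ], strata, labs, st$met), "No cases")
})
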