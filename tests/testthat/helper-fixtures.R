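# fixtures built in code: record builders and random matched sets

# a composition record; defaults are an unambiguous dust-day profile
make_record <- function(site_id = "S1", date = as.Date("2011-05-10"),
                        pm10 = 59.4, pm25 = 12.5,
                        Si = 2.0, Ca = 0.6, K = 0.3, Fe = 0.6, Ti = 0.08,
                        As = 0.001, Zn = 0.002, Cu = 0.0008, Pb = 0.0005,
                        SO4 = 0.85, NO3 = 0.32, OC = 0.65, EC = 0.036) {
  tibble::tibble(
    site_id = site_id, date = date, pm10 = pm10, pm25 = pm25,
    Si = Si, Ca = Ca, K = K, Fe = Fe, Ti = Ti, As = As, Zn = Zn,
    Cu = Cu, Pb = Pb, SO4 = SO4, NO3 = NO3, OC = OC, EC = EC
  )
}

# an unambiguous non-dust profile
make_nondust_record <- function(...) {
  make_record(pm10 = 8.5, pm25 = 3.5, Si = 0.19, Ca = 0.06, K = 0.05,
              Fe = 0.05, Ti = 0.005, As = 0.002, Zn = 0.01, Cu = 0.008,
              Pb = 0.005, SO4 = 0.62, NO3 = 0.36, OC = 0.61, EC = 0.12, ...)
}

# random small matched sets in the matched_sets column layout;
# n_extra extra continuous covariates named x1, x2, ...
rand_sets <- function(n_sets, seed = 1, size = 4, n_extra = 0,
                      p_exposed = 0.3, weight = NULL) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_sets), function(s) {
      expo <- stats::rbinom(size, 1, p_exposed)
      case <- sample.int(size, 1)
      out <- tibble::tibble(
        set_id = sprintf("set%04d", s),
        member_date = as.Date("2010-01-01") + 24 * (s - 1) + 6 * (seq_len(size) - 1),
        is_case = seq_len(size) == case,
        exposure = as.numeric(expo),
        weight = if (is.null(weight)) 1 else weight[s]
      )
      for (k in seq_len(n_extra)) out[[paste0("x", k)]] <- stats::rnorm(size)
      out
    })
    dplyr::bind_rows(rows)
  })
}

# brute-force scalar conditional log-likelihood, independent of the
# package kernel: direct sum over sets of eta_case - log sum exp(eta)
brute_loglik_scalar <- function(beta, sets) {
  sum(vapply(split(sets, sets$set_id), function(s) {
    eta <- beta * s$exposure
    w <- s$weight[1]
    w * (eta[s$is_case] - log(sum(exp(eta))))
  }, numeric(1)))
}

# small synthetic study shared by integration-style tests
small_study <- function(seed = 42, years = 2, ...) {
  cfg <- sim_config(
    seed = seed, date_start = "2010-01-01",
    date_end = sprintf("%d-12-31", 2009 + years), ...
  )
  list(cfg = cfg, study = sim_study(cfg))
}
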