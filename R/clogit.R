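# Weighted conditional logistic regression for matched case-referent
# sets. The conditional log-likelihood is
#   l(beta) = sum_s w_s [ eta_case(s) - log sum_{i in s} exp(eta_i) ]
# with eta = X beta. Gradient and Hessian are analytic; the optimizer is
# Newton-Raphson with step-halving from beta = 0.

prepare_set_matrix <- function(sets, terms = NULL, dust_term = "exposure") {
  sets <- dplyr::arrange(as_tibble(sets), .data$set_id, .data$member_date)
  bookkeeping <- c("set_id", "zip_id", "site_id", "case_date", "member_date",
                   "is_case", "weight", "outcome")
  if (is.null(terms)) terms <- setdiff(names(sets), bookkeeping)
  if (!dust_term %in% terms) {
    abort(paste0("Dust term `", dust_term, "` not among model terms."))
  }
  X <- as.matrix(sets[terms])
  if (!is.numeric(X)) abort("Model terms must be numeric.")
  if (any(!is.finite(X))) abort("Non-finite covariate value in model terms.")
  set_f <- factor(sets$set_id, levels = unique(sets$set_id))
  set <- as.integer(set_f)
  S <- nlevels(set_f)
  is_case <- as.logical(sets$is_case)
  cases_per_set <- tabulate(set[is_case], nbins = S)
  if (any(cases_per_set != 1L)) {
    abort("Every set must contain exactly one case row.")
  }
  w_set <- as.numeric(tapply(sets$weight, set, function(x) x[1]))
  if (any(w_set < 1)) abort("Set weights must be >= 1.")
  list(X = X, set = set, S = S, is_case = is_case, w_set = w_set,
       terms = terms, sets = sets)
}

loglik_kernel <- function(beta, X, set, is_case, w_set, want_hessian = TRUE) {
  eta <- drop(X %*% beta)
  mx <- stats::ave(eta, set, FUN = max)
  ex <- exp(eta - mx)
  denom <- drop(rowsum(ex, set)) # rows ordered by set index 1..S
  p <- ex / denom[set]
  eta_case <- drop(rowsum(eta * is_case, set))
  mx_set <- drop(rowsum(mx * is_case, set))
  value <- sum(w_set * (eta_case - (log(denom) + mx_set)))
  w_row <- w_set[set]
  grad <- drop(crossprod(X, w_row * (is_case - p)))
  if (!want_hessian) return(list(value = value, gradient = grad))
  M <- rowsum(X * p, set) # S x p, row s = mu_s'
  hess <- -(crossprod(X * sqrt(w_row * p)) - crossprod(M * sqrt(w_set)))
  list(value = value, gradient = grad, hessian = hess)
}

#' Conditional log-likelihood, gradient, and Hessian
#'
#' Evaluates the weighted conditional logistic log-likelihood of matched
#' sets at `beta`, with exact analytic first and second derivatives.
#'
#' @param beta Coefficient vector (length = number of terms).
#' @param sets A `matched_sets` tibble ([assemble_sets()]).
#' @param terms Model term columns; default: every non-bookkeeping column.
#' @param dust_term Name of the exposure term.
#' @return List: `value`, `gradient`, `hessian`.
#' @export
#' @examples
#' # one set: exposed case vs three unexposed referents, beta = log 2
#' s <- tibble::tibble(set_id = 1, member_date = as.Date("2010-01-01") + c(0, 6, 12, 18),
#'                     is_case = c(TRUE, FALSE, FALSE, FALSE),
#'                     exposure = c(1, 0, 0, 0), weight = 1)
#' clogit_loglik(log(2), s)$value # log(2/5)
clogit_loglik <- function(beta, sets, terms = NULL, dust_term = "exposure") {
  pr <- prepare_set_matrix(sets, terms, dust_term)
  if (length(beta) != ncol(pr$X)) {
    abort(sprintf("`beta` has length %d but the model has %d term(s).",
                  length(beta), ncol(pr$X)))
  }
  loglik_kernel(beta, pr$X, pr$set, pr$is_case, pr$w_set)
}

# columns with no within-set variation carry no conditional information
aliased_columns <- function(X, set) {
  ctr <- X - rowsum(X, set)[set, , drop = FALSE] /
    tabulate(set)[set]
  apply(abs(ctr), 2, max) < 1e-12
}

#' Fit conditional logistic regression to matched sets
#'
#' Newton-Raphson with step-halving from `beta = 0`, convergence on the
#' gradient infinity norm, standard errors from the inverse observed
#' information at the optimum. Numeric covariates are centred and scaled
#' internally to condition the Hessian; coefficients are reported on the
#' original scale. Terms with no within-set variation are aliased
#' (coefficient `NA`); a dust term with no within-set variation anywhere
#' (no discordant set) is a non-identifiability error. Complete
#' separation of the dust term is detected and flagged instead of being
#' reported as a finite estimate.
#'
#' @inheritParams clogit_loglik
#' @param tol Convergence tolerance on the gradient infinity norm,
#'   relative to total set weight.
#' @param max_iter Maximum Newton iterations.
#' @param conf_level Wald confidence level for the dust odds ratio.
#' @return Object of class `dustcase_clogit`: coefficients, vcov, loglik,
#'   n_sets, converged, iterations, dust_or with CI, separation_flag,
#'   singular_flag.
#' @export
fit_clogit <- function(sets, terms = NULL, dust_term = "exposure",
                       tol = 1e-8, max_iter = 100L, conf_level = 0.95) {
  pr <- prepare_set_matrix(sets, terms, dust_term)
  X <- pr$X
  p_all <- ncol(X)
  aliased <- aliased_columns(X, pr$set)
  if (aliased[[dust_term]]) {
    abort(paste0("Term `", dust_term, "` is non-identifiable: no set is ",
                 "discordant in it (no within-set variation anywhere)."))
  }
  keep <- !aliased
  Xk <- X[, keep, drop = FALSE]
  # standardize non-binary columns (scale only affects the coefficient
  # scale; centring is absorbed by the conditional likelihood)
  is_binary <- apply(Xk, 2, function(x) all(x %in% c(0, 1)))
  ctr <- ifelse(is_binary, 0, colMeans(Xk))
  scl <- ifelse(is_binary, 1, apply(Xk, 2, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(Xk, 2, ctr), 2, scl, "/")

  beta <- rep(0, ncol(Xs))
  gtol <- tol * max(1, sum(pr$w_set))
  cur <- loglik_kernel(beta, Xs, pr$set, pr$is_case, pr$w_set)
  converged <- FALSE
  separation <- FALSE
  singular <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(-cur$hessian, cur$gradient), error = function(e) NULL)
    if (is.null(step)) {
      singular <- TRUE
      step <- drop(MASS::ginv(-cur$hessian) %*% cur$gradient)
    }
    # step-halving: insist on non-decreasing log-likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      nxt <- loglik_kernel(cand, Xs, pr$set, pr$is_case, pr$w_set)
      if (is.finite(nxt$value) && nxt$value >= cur$value - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 2^-20) break
    }
    beta <- beta + lambda * step
    cur <- nxt
    if (max(abs(cur$gradient)) <= gtol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 15 && max(abs(cur$gradient)) > gtol) {
      separation <- TRUE
      break
    }
  }
  info <- -cur$hessian
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V)) {
    singular <- TRUE
    warn("Observed information is singular; using pseudo-inverse standard errors.")
    V <- MASS::ginv(info)
  }
  # back to the original covariate scale
  beta_orig <- beta / scl
  V_orig <- V / tcrossprod(scl)
  coef_full <- setNames(rep(NA_real_, p_all), pr$terms)
  coef_full[keep] <- beta_orig
  V_full <- matrix(NA_real_, p_all, p_all, dimnames = list(pr$terms, pr$terms))
  V_full[keep, keep] <- V_orig
  z <- qnorm(1 - (1 - conf_level) / 2)
  b_dust <- coef_full[[dust_term]]
  se_dust <- sqrt(V_full[dust_term, dust_term])
  if (separation) {
    warn(paste0("Apparent complete separation in `", dust_term,
                "`; odds ratio not reported."))
  }
  dust_or <- if (separation) c(or = NA_real_, low = NA_real_, high = NA_real_)
  else c(
    or = exp(b_dust),
    low = exp(b_dust - z * se_dust),
    high = exp(b_dust + z * se_dust)
  )
  structure(
    list(
      coefficients = coef_full, vcov = V_full, loglik = cur$value,
      n_sets = pr$S, n_obs = nrow(pr$sets),
      n_dropped = (attr(sets, "n_dropped_exposure") %||% 0L) +
        (attr(sets, "n_dropped_met") %||% 0L),
      converged = converged, iterations = iter,
      dust_term = dust_term, dust_or = dust_or,
      conf_level = conf_level,
      separation_flag = separation, singular_flag = singular,
      aliased = aliased
    ),
    class = "dustcase_clogit"
  )
}

#' @export
print.dustcase_clogit <- function(x, ...) {
  cat("<conditional logistic fit>\n")
  cat(sprintf("  sets: %d  loglik: %.4f  converged: %s (%d iter)\n",
              x$n_sets, x$loglik, x$converged, x$iterations))
  if (x$separation_flag) cat("  WARNING: complete separation detected\n")
  cat(sprintf("  %s OR: %.4f (%.0f%% CI %.4f, %.4f)\n", x$dust_term,
              x$dust_or[["or"]], 100 * x$conf_level,
              x$dust_or[["low"]], x$dust_or[["high"]]))
  invisible(x)
}

#' @export
coef.dustcase_clogit <- function(object, ...) object$coefficients

#' @export
vcov.dustcase_clogit <- function(object, ...) object$vcov

#' Tidy a conditional logistic fit
#'
#' @param x A `dustcase_clogit` object.
#' @param exponentiate Report odds-ratio scale estimates and intervals.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.dustcase_clogit <- function(x, exponentiate = FALSE, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a conditional logistic fit
#'
#' @inheritParams tidy.dustcase_clogit
#' @return One-row tibble of fit-level summaries.
#' @export
glance.dustcase_clogit <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_sets = x$n_sets, n_obs = x$n_obs,
    converged = x$converged, iterations = x$iterations,
    separation = x$separation_flag, singular = x$singular_flag
  )
}

#' Lag-specific odds-ratio profile
#'
#' Fits an independent single-lag conditional logistic model for each
#' requested lag: sets are re-assembled per lag (each lag aligns with a
#' different slice of the monitor sampling cycle), collapsed, and fitted.
#' Optionally repeats the fits within groups (e.g. a state column).
#'
#' @param cases Case tibble from [select_visits()] (or compatible).
#' @param strata [build_strata()] output covering the case dates.
#' @param labels Site-day dust label table.
#' @param met ZIP-day meteorology.
#' @param lags Integer lags to profile (subset of 0..5).
#' @param group Optional name of a grouping column in `cases`; fits are
#'   repeated per group level in addition to the pooled fit.
#' @inheritParams assemble_sets
#' @inheritParams fit_clogit
#' @return Tibble of class `dustcase_lag_profile`: group, lag, or,
#'   ci_low, ci_high, beta, se, n_sets, converged, separation.
#' @export
lag_profile <- function(cases, strata, labels, met, lags = 0:5,
                        holidays = NULL, adjust_pollutants = FALSE,
                        group = NULL, quiet = TRUE, conf_level = 0.95) {
  if (nrow(cases) == 0) abort("No cases supplied; nothing to profile.")
  if (!all(lags %in% 0:5)) abort("`lags` must be a subset of 0..5.")
  groups <- list(all = cases)
  if (!is.null(group)) {
    lv <- split(cases, cases[[group]])
    groups <- c(groups, lv)
  }
  rows <- purrr::imap(groups, function(gc, gname) {
    purrr::map(lags, function(lg) {
      sets <- assemble_sets(gc, strata, labels, met, lag = lg,
                            holidays = holidays,
                            adjust_pollutants = adjust_pollutants,
                            quiet = quiet)
      sets <- collapse_sets(sets)
      fit <- tryCatch(
        fit_clogit(sets, conf_level = conf_level),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        return(tibble(
          group = gname, lag = lg, or = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, beta = NA_real_, se = NA_real_,
          n_sets = attr(sets, "n_sets") %||% 0L,
          converged = FALSE, separation = NA,
          note = conditionMessage(fit)
        ))
      }
      b <- fit$coefficients[[fit$dust_term]]
      tibble(
        group = gname, lag = lg,
        or = fit$dust_or[["or"]], ci_low = fit$dust_or[["low"]],
        ci_high = fit$dust_or[["high"]],
        beta = b, se = sqrt(fit$vcov[fit$dust_term, fit$dust_term]),
        n_sets = fit$n_sets, converged = fit$converged,
        separation = fit$separation_flag, note = NA_character_
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dustcase_lag_profile", class(out))
  out
}

#' Plot a lag-specific odds-ratio profile
#'
#' Odds ratio with Wald interval against lag, one panel per group.
#'
#' @param object A `dustcase_lag_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dustcase_lag_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$or)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)
    ) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Lag (days)", y = "Odds ratio (95% CI)") +
    ggplot2::theme_bw()
}
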