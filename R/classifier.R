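# Five-criteria dust-storm-day classifier for speciated PM records:
# (1) high PM10 and PM2.5 mass, (2) low PM2.5/PM10 ratio, (3) high
# crustal elements (Si, Ca, K, Fe, Ti), (4) low anthropogenic species
# (As, Zn, Cu, Pb, SO4, NO3, OC, EC), (5) low crustal enrichment factors
# of Zn, Cu, Pb, K relative to a reference element (default Fe).
# All comparisons are inclusive (>= floors, <= ceilings).

CRUSTAL_ELEMENTS <- c("Si", "Ca", "K", "Fe", "Ti")
ANTHRO_SPECIES <- c("As", "Zn", "Cu", "Pb", "SO4", "NO3", "OC", "EC")
EF_ELEMENTS <- c("Zn", "Cu", "Pb", "K")

#' Average upper-continental-crust mass fractions
#'
#' Elemental mass fractions of average upper continental crust used as
#' the denominator of crustal enrichment factors. The table is a plain
#' tibble and can be replaced wholesale in [classifier_config()].
#'
#' @return Tibble with columns `element` and `mass_fraction`.
#' @export
#' @examples
#' crustal_abundances()
crustal_abundances <- function() {
  tibble::tribble(
    ~element, ~mass_fraction,
    "Si", 3.11e-01,
    "Ca", 2.57e-02,
    "K",  2.32e-02,
    "Fe", 3.53e-02,
    "Ti", 3.84e-03,
    "As", 4.8e-06,
    "Zn", 6.7e-05,
    "Cu", 2.8e-05,
    "Pb", 1.7e-05
  )
}

#' Configuration of the five-criteria dust-day classifier
#'
#' Thresholds for each criterion, with defaults calibrated so that a
#' dust-storm composition profile (tens of ug/m3 of coarse-dominated PM,
#' ~2 ug/m3 of fine silicon, near-crustal trace-metal ratios) labels 1
#' and a clean rural background profile labels 0. All comparisons are
#' inclusive: a value exactly at a floor or ceiling passes.
#'
#' @param pm10_min,pm25_min Criterion 1 mass floors, ug/m3.
#' @param ratio_max Criterion 2 ceiling on PM2.5/PM10.
#' @param crustal_mode `"sum"` (default) tests Si+Ca+K+Fe+Ti against
#'   `crustal_min`; `"per_element"` tests each element against
#'   `crustal_min_elements`.
#' @param crustal_min Floor on the summed crustal concentration, ug/m3.
#' @param crustal_min_elements Named per-element floors (per-element mode).
#' @param anthro_max Named ceilings for the anthropogenic species, ug/m3
#'   in absolute mode.
#' @param anthro_mode `"absolute"` (default) compares concentrations to
#'   `anthro_max`; `"fraction"` compares to `anthro_max * pm25` (ceilings
#'   read as fractions of PM2.5 mass).
#' @param ef_max Criterion 5 ceiling on the crustal enrichment factor.
#' @param ef_elements Elements whose enrichment is tested.
#' @param crust_ref_element Reference element for enrichment (default Fe).
#' @param crust_abundances Crustal mass-fraction table, see
#'   [crustal_abundances()].
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(pm10_min = 30,
                              pm25_min = 4,
                              ratio_max = 0.45,
                              crustal_mode = c("sum", "per_element"),
                              crustal_min = 1.2,
                              crustal_min_elements = c(
                                Si = 0.8, Ca = 0.2, K = 0.1, Fe = 0.2, Ti = 0.02
                              ),
                              anthro_max = c(
                                As = 0.01, Zn = 0.08, Cu = 0.05, Pb = 0.05,
                                SO4 = 3.0, NO3 = 1.5, OC = 2.5, EC = 0.25
                              ),
                              anthro_mode = c("absolute", "fraction"),
                              ef_max = 10,
                              ef_elements = EF_ELEMENTS,
                              crust_ref_element = "Fe",
                              crust_abundances = crustal_abundances()) {
  crustal_mode <- match.arg(crustal_mode)
  anthro_mode <- match.arg(anthro_mode)
  thr <- c(pm10_min, pm25_min, ratio_max, crustal_min, crustal_min_elements,
           anthro_max, ef_max)
  if (any(thr <= 0)) abort("All classifier thresholds must be > 0.")
  ab <- setNames(crust_abundances$mass_fraction, crust_abundances$element)
  if (!crust_ref_element %in% names(ab)) {
    abort(paste0("Reference element `", crust_ref_element,
                 "` has no crustal abundance."))
  }
  missing_ab <- setdiff(ef_elements, names(ab))
  if (length(missing_ab)) {
    abort(paste0("No crustal abundance for enrichment element(s): ",
                 paste(missing_ab, collapse = ", ")))
  }
  if (!all(CRUSTAL_ELEMENTS %in% names(crustal_min_elements)) &&
      crustal_mode == "per_element") {
    abort("`crustal_min_elements` must name all of Si, Ca, K, Fe, Ti.")
  }
  structure(
    list(
      pm10_min = pm10_min, pm25_min = pm25_min, ratio_max = ratio_max,
      crustal_mode = crustal_mode, crustal_min = crustal_min,
      crustal_min_elements = crustal_min_elements,
      anthro_max = anthro_max, anthro_mode = anthro_mode,
      ef_max = ef_max, ef_elements = ef_elements,
      crust_ref_element = crust_ref_element, abundances = ab
    ),
    class = "classifier_config"
  )
}

col_or_na <- function(df, nm) {
  if (nm %in% names(df)) df[[nm]] else rep(NA_real_, nrow(df))
}

validate_records <- function(records) {
  records <- as_tibble(records)
  if (!all(c("site_id", "date") %in% names(records))) {
    abort("Monitor records need `site_id` and `date` columns.")
  }
  records$date <- as_iso_date(records$date, "date")
  conc_cols <- intersect(
    c("pm10", "pm25", "pm_coarse", CRUSTAL_ELEMENTS, ANTHRO_SPECIES),
    names(records)
  )
  for (nm in conc_cols) {
    bad <- which(records[[nm]] < 0)
    if (length(bad)) {
      abort(paste0("Negative concentration in column `", nm, "` at row(s) ",
                   paste(head(bad, 5), collapse = ", "), "."))
    }
  }
  if (!"pm_coarse" %in% names(records)) {
    records$pm_coarse <- records$pm10 - records$pm25
  }
  # records violating pm25 <= pm10 are flagged, never silently corrected
  records$mass_inconsistent <- !is.na(records$pm10) & !is.na(records$pm25) &
    records$pm25 > records$pm10 + 1e-9
  records
}

#' Crustal enrichment factor of an element
#'
#' EF = (C_element / C_ref) in the sample divided by (A_element / A_ref)
#' in average upper crust. Values near 1 indicate crustal (natural)
#' origin; strongly enriched values indicate anthropogenic sources.
#' Returns `NA` where the element or reference concentration is missing
#' or the reference concentration is zero.
#'
#' @param records Monitor record tibble (one column per species).
#' @param element Element name (must have a crustal abundance).
#' @param cfg A [classifier_config()].
#' @return Numeric vector of enrichment factors, one per record.
#' @export
#' @examples
#' rec <- tibble::tibble(site_id = "A", date = as.Date("2010-01-01"),
#'                       pm10 = 50, pm25 = 10, Zn = 0.002, Fe = 0.6)
#' enrichment_factor(rec, "Zn", classifier_config())
enrichment_factor <- function(records, element, cfg = classifier_config()) {
  if (!element %in% names(cfg$abundances)) {
    abort(paste0("Element `", element, "` has no crustal abundance configured."))
  }
  c_el <- col_or_na(records, element)
  c_ref <- col_or_na(records, cfg$crust_ref_element)
  ef <- (c_el / c_ref) /
    (cfg$abundances[[element]] / cfg$abundances[[cfg$crust_ref_element]])
  ef[!is.na(c_ref) & c_ref == 0] <- NA_real_
  ef
}

# three-valued "all of these hold": TRUE if all pass with none missing;
# FALSE as soon as one present value fails; NA otherwise
all3 <- function(mat_pass) {
  any_fail <- rowSums(!mat_pass, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(mat_pass)) > 0
  out <- rep(TRUE, nrow(mat_pass))
  out[any_na] <- NA
  out[any_fail] <- FALSE
  out
}

#' Classify site-days as dust storm days
#'
#' Applies the five criteria to each record and returns the dichotomous
#' dust indicator with a per-criterion trace. The label is 1 only when
#' all five criteria pass; 0 when any criterion fails on present inputs;
#' `NA` when a criterion that would decide the label cannot be evaluated
#' because an input is missing.
#'
#' @param records Monitor record tibble: `site_id`, `date`, `pm10`,
#'   `pm25`, optional `pm_coarse`, one column per species. Missing values
#'   allowed anywhere; negative concentrations are rejected.
#' @param cfg A [classifier_config()].
#' @return Tibble: site_id, date, dust (integer 0/1/NA), crit1..crit5
#'   (logical trace), mass_inconsistent flag.
#' @export
classify_days <- function(records, cfg = classifier_config()) {
  records <- validate_records(records)
  n <- nrow(records)
  pm10 <- col_or_na(records, "pm10")
  pm25 <- col_or_na(records, "pm25")

  crit1 <- pm10 >= cfg$pm10_min & pm25 >= cfg$pm25_min
  ratio <- pm25 / pm10
  ratio[is.nan(ratio) | is.infinite(ratio)] <- NA_real_
  crit2 <- ratio <= cfg$ratio_max

  cr <- vapply(CRUSTAL_ELEMENTS, function(el) col_or_na(records, el),
               numeric(n))
  cr <- matrix(cr, nrow = n)
  if (cfg$crustal_mode == "sum") {
    s_present <- rowSums(cr, na.rm = TRUE)
    any_na <- rowSums(is.na(cr)) > 0
    # monotone shortcut: a partial sum already at the floor passes
    crit3 <- rep(NA, n)
    crit3[s_present >= cfg$crustal_min] <- TRUE
    crit3[!any_na & s_present < cfg$crustal_min] <- FALSE
  } else {
    mins <- cfg$crustal_min_elements[CRUSTAL_ELEMENTS]
    crit3 <- all3(sweep(cr, 2, mins, ">="))
  }

  anth_names <- names(cfg$anthro_max)
  an <- vapply(anth_names, function(sp) col_or_na(records, sp), numeric(n))
  an <- matrix(an, nrow = n)
  ceilings <- if (cfg$anthro_mode == "absolute") {
    matrix(cfg$anthro_max, nrow = n, ncol = length(anth_names), byrow = TRUE)
  } else {
    outer(pm25, cfg$anthro_max)
  }
  crit4 <- all3(an <= ceilings)

  efs <- vapply(cfg$ef_elements, function(el) enrichment_factor(records, el, cfg),
                numeric(n))
  efs <- matrix(efs, nrow = n)
  crit5 <- all3(efs <= cfg$ef_max)

  trace <- cbind(crit1, crit2, crit3, crit4, crit5)
  dust <- rep(1L, n)
  dust[rowSums(is.na(trace)) > 0] <- NA_integer_
  dust[rowSums(!trace, na.rm = TRUE) > 0] <- 0L

  tibble(
    site_id = records$site_id, date = records$date, dust = dust,
    crit1 = crit1, crit2 = crit2, crit3 = crit3, crit4 = crit4, crit5 = crit5,
    mass_inconsistent = records$mass_inconsistent
  )
}

#' @rdname classify_days
#' @param record A single monitor record (one-row data frame or named list).
#' @export
classify_day <- function(record, cfg = classifier_config()) {
  classify_days(as_tibble(record), cfg)
}

#' Classify a monitor series over a full calendar
#'
#' Evaluates [classify_days()] on the sampled records and expands the
#' result to every (site, day) of the requested range; days with no
#' measurement get a missing dust indicator.
#'
#' @inheritParams classify_days
#' @param date_start,date_end Calendar range to cover (defaults to the
#'   record range).
#' @return Tibble with one row per site and day: site_id, date, dust,
#'   sampled, crit1..crit5.
#' @export
classify_series <- function(records, cfg = classifier_config(),
                            date_start = NULL, date_end = NULL) {
  records <- as_tibble(records)
  records$date <- as_iso_date(records$date, "date")
  dup <- duplicated(records[c("site_id", "date")])
  if (any(dup)) {
    abort(paste0("Duplicate (site_id, date) record(s), e.g. ",
                 records$site_id[dup][1], " ", format(records$date[dup][1]), "."))
  }
  date_start <- as_iso_date(date_start %||% min(records$date), "date_start")
  date_end <- as_iso_date(date_end %||% max(records$date), "date_end")
  labels <- classify_days(records, cfg)
  grid <- tidyr::expand_grid(
    site_id = sort(unique(records$site_id)),
    date = seq(date_start, date_end, by = 1)
  )
  out <- dplyr::left_join(grid, labels, by = c("site_id", "date"))
  out$sampled <- paste(out$site_id, out$date) %in%
    paste(records$site_id, records$date)
  dplyr::relocate(out, "sampled", .after = "dust")
}
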