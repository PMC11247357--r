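# ICD-based outcome ascertainment. Codes are matched in any diagnosis
# position; ranges are compared on the 3-character ICD category
# (zero-padded numeric for ICD-9, letter + two digits for ICD-10) and
# prefixes by startsWith. The ICD era of a code is determined by its
# alphabet; codes whose alphabet conflicts with the date-implied era
# (9 before 1 Oct 2015, 10 on/after) are flagged and matched by alphabet.

ICD10_SWITCH <- as.Date("2015-10-01")

#' Built-in cardiorespiratory outcome definitions
#'
#' Category-level ICD-9 and ICD-10 patterns for all respiratory disease
#' (RD), asthma, COPD, all cardiovascular disease (CVD), ischaemic heart
#' disease (IHD), cardiac dysrhythmia (DYS), and congestive heart
#' failure (CHF). Each pattern is a category prefix (`"493"`, `"J45"`)
#' or an inclusive category range (`"460-519"`, `"J41-J44"`).
#'
#' @return Named list of outcome definitions (class `outcome_def`), each
#'   with `name`, `icd9`, `icd10`.
#' @export
#' @examples
#' names(outcome_definitions())
#' outcome_definitions()$RD
outcome_definitions <- function() {
  def <- function(name, icd9, icd10) {
    structure(list(name = name, icd9 = icd9, icd10 = icd10),
              class = "outcome_def")
  }
  list(
    RD     = def("RD", "460-519", "J00-J99"),
    ASTHMA = def("ASTHMA", "493", "J45"),
    COPD   = def("COPD", c("491", "492", "496"), "J41-J44"),
    CVD    = def("CVD", "390-459", "I00-I99"),
    IHD    = def("IHD", "410-414", "I20-I25"),
    DYS    = def("DYS", "427", "I47-I49"),
    CHF    = def("CHF", "428", c("I42", "I50", "I51"))
  )
}

#' @export
print.outcome_def <- function(x, ...) {
  cat("<outcome_def>", x$name, "\n")
  cat("  ICD-9 :", paste(x$icd9, collapse = ", "), "\n")
  cat("  ICD-10:", paste(x$icd10, collapse = ", "), "\n")
  invisible(x)
}

resolve_outcome <- function(outcome) {
  if (inherits(outcome, "outcome_def")) return(outcome)
  defs <- outcome_definitions()
  if (is.character(outcome) && outcome %in% names(defs)) return(defs[[outcome]])
  abort(paste0("Unknown outcome `", as.character(outcome)[1],
               "`; expected one of ", paste(names(defs), collapse = ", "),
               " or an `outcome_def`."))
}

# ordinal of a 3-character ICD category: plain integer for ICD-9,
# letter-block * 100 + number for ICD-10 (so J41 < J44 < K00)
category_ordinal <- function(cat3, era) {
  if (era == 9L) {
    suppressWarnings(as.integer(cat3))
  } else {
    letter <- match(toupper(substr(cat3, 1, 1)), LETTERS)
    num <- suppressWarnings(as.integer(substr(cat3, 2, 3)))
    letter * 100L + num
  }
}

# logical: does each code match any pattern of its era?
codes_match_patterns <- function(codes, patterns, era) {
  cat3 <- toupper(substr(codes, 1, 3))
  ord <- category_ordinal(cat3, era)
  out <- rep(FALSE, length(codes))
  for (p in patterns) {
    if (grepl("-", p, fixed = TRUE)) {
      lohi <- strsplit(p, "-", fixed = TRUE)[[1]]
      lo <- category_ordinal(toupper(lohi[1]), era)
      hi <- category_ordinal(toupper(lohi[2]), era)
      out <- out | (!is.na(ord) & ord >= lo & ord <= hi)
    } else {
      out <- out | startsWith(toupper(codes), toupper(p))
    }
  }
  out
}

dx_columns <- function(visits) {
  cols <- grep("^dx", names(visits), value = TRUE)
  if (!length(cols)) abort("`visits` must have diagnosis columns named dx1, dx2, ...")
  cols
}

#' Does a visit match an outcome definition?
#'
#' A visit matches if any diagnosis code, primary or secondary, matches
#' a pattern of the code's ICD era. Malformed codes (empty, or starting
#' with neither digit nor letter+digit) are skipped with a warning.
#'
#' @param visits Visit tibble: `visit_id`, `admission_date`, `zip_id`,
#'   diagnosis columns `dx1`...`dxK` (NA allowed beyond the first).
#' @param outcome An outcome name (see [outcome_definitions()]) or an
#'   `outcome_def`.
#' @param warn_era_conflicts Warn when a code's alphabet disagrees with
#'   the era implied by the admission date.
#' @return Logical vector, one per visit.
#' @export
#' @examples
#' v <- tibble::tibble(visit_id = "1", admission_date = as.Date("2016-02-01"),
#'                     zip_id = "Z", dx1 = "R05", dx2 = "I48")
#' matches_outcome(v, "DYS")
matches_outcome <- function(visits, outcome, warn_era_conflicts = TRUE) {
  outcome <- resolve_outcome(outcome)
  visits <- as_tibble(visits)
  visits$admission_date <- as_iso_date(visits$admission_date, "admission_date")
  cols <- dx_columns(visits)
  codes <- as.matrix(visits[cols])
  n <- nrow(visits)
  date_era <- ifelse(visits$admission_date >= ICD10_SWITCH, 10L, 9L)
  hit <- rep(FALSE, n)
  n_malformed <- 0L
  n_conflict <- 0L
  for (j in seq_along(cols)) {
    code <- codes[, j]
    present <- !is.na(code) & nzchar(code)
    is9 <- present & grepl("^[0-9]", code)
    is10 <- present & grepl("^[A-Za-z][0-9]", code)
    n_malformed <- n_malformed + sum(present & !is9 & !is10)
    n_conflict <- n_conflict +
      sum((is9 & date_era == 10L) | (is10 & date_era == 9L))
    hit[is9] <- hit[is9] | codes_match_patterns(code[is9], outcome$icd9, 9L)
    hit[is10] <- hit[is10] | codes_match_patterns(code[is10], outcome$icd10, 10L)
  }
  if (n_malformed > 0) {
    warn(paste0(n_malformed, " malformed diagnosis code(s) skipped."))
  }
  if (n_conflict > 0 && warn_era_conflicts) {
    warn(paste0(n_conflict, " code(s) whose alphabet conflicts with the ",
                "date-implied ICD era; matched by alphabet."))
  }
  hit
}

#' Select analysable visits for one outcome
#'
#' Retains visits that match the outcome definition and whose residential
#' ZIP is linked to a monitor, attaches the linked `site_id`, preserves
#' input order, and reports kept/dropped counts.
#'
#' @inheritParams matches_outcome
#' @param linkage Output of [assign_sites()].
#' @param quiet Suppress the kept/dropped message.
#' @return The retained visits with `site_id` and `outcome` columns and
#'   attributes `n_input`, `n_matched`, `n_kept`.
#' @export
select_visits <- function(visits, outcome, linkage, quiet = FALSE,
                          warn_era_conflicts = TRUE) {
  outcome <- resolve_outcome(outcome)
  m <- matches_outcome(visits, outcome, warn_era_conflicts = warn_era_conflicts)
  out <- visits[m, , drop = FALSE]
  out$site_id <- linkage$site_id[match(out$zip_id, linkage$zip_id)]
  linked <- !is.na(out$site_id)
  kept <- out[linked, , drop = FALSE]
  kept$outcome <- outcome$name
  if (!quiet) {
    inform(sprintf(
      "%s: %d of %d visits match; %d kept (linked ZIP), %d dropped (unlinked).",
      outcome$name, sum(m), nrow(visits), nrow(kept), sum(!linked)
    ))
  }
  attr(kept, "n_input") <- nrow(visits)
  attr(kept, "n_matched") <- sum(m)
  attr(kept, "n_kept") <- nrow(kept)
  kept
}
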