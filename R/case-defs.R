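#' Case definitions by tumour behaviour and histotype
#'
#' A case definition is a pure predicate over cohort records selecting which
#' cases enter an outcome analysis (controls always enter), plus a per-study
#' minimum case count: studies must contribute strictly more than
#' `min_cases_per_study` qualifying cases or they are excluded from that
#' outcome.
#'
#' Registered labels:
#' \describe{
#'   \item{all}{every case, any behaviour (including unknown).}
#'   \item{invasive}{invasive tumours.}
#'   \item{borderline}{borderline (low malignant potential) tumours.}
#'   \item{high_grade_serous}{invasive serous excluding low-grade (G1),
#'     plus invasive serous of unknown grade, plus primary peritoneal
#'     tumours of unknown behaviour (the large majority of both are
#'     high-grade serous).}
#'   \item{lowgrade_borderline_serous}{invasive low-grade serous plus
#'     borderline serous.}
#'   \item{mucinous}{mucinous tumours of any behaviour.}
#'   \item{endometrioid}{invasive endometrioid tumours.}
#'   \item{clear_cell}{invasive clear cell tumours.}
#' }
#'
#' @param label one of the registered labels.
#' @param min_cases_per_study strict lower bound on qualifying cases per
#'   study (default 5, i.e. studies need > 5 cases).
#' @return an object of class `case_definition` with fields `label`,
#'   `predicate` (function over a cohort data.frame returning a logical
#'   vector), `min_cases_per_study`.
#' @export
case_definition <- function(label, min_cases_per_study = 5L) {
  defs <- case_definition_registry()
  if (!label %in% names(defs)) {
    stop_bad_arg("label", paste("unknown case definition; available:",
                                paste(names(defs), collapse = ", ")))
  }
  out <- list(label = label, predicate = defs[[label]],
              min_cases_per_study = as.integer(min_cases_per_study))
  class(out) <- "case_definition"
  out
}

#' @rdname case_definition
#' @export
available_case_definitions <- function() names(case_definition_registry())

case_definition_registry <- function() {
  is_case <- function(co) !is.na(co$status) & co$status == 1
  beh <- function(co, b) is_case(co) & !is.na(co$behaviour) & co$behaviour == b
  hist_is <- function(co, h) !is.na(co$histotype) & co$histotype == h
  list(
    all = is_case,
    invasive = function(co) beh(co, "invasive"),
    borderline = function(co) beh(co, "borderline"),
    high_grade_serous = function(co) {
      serous_inv <- beh(co, "invasive") & hist_is(co, "serous")
      not_g1 <- is.na(co$grade) | co$grade != "low"
      peritoneal_unknown <- beh(co, "unknown") & !is.na(co$site) &
        co$site == "peritoneal"
      (serous_inv & not_g1) | peritoneal_unknown
    },
    lowgrade_borderline_serous = function(co) {
      (beh(co, "invasive") & hist_is(co, "serous") & !is.na(co$grade) &
         co$grade == "low") |
        (beh(co, "borderline") & hist_is(co, "serous"))
    },
    mucinous = function(co) {
      (beh(co, "invasive") | beh(co, "borderline")) & hist_is(co, "mucinous")
    },
    endometrioid = function(co) beh(co, "invasive") & hist_is(co, "endometrioid"),
    clear_cell = function(co) beh(co, "invasive") & hist_is(co, "clear_cell")
  )
}

# Restrict a cohort to controls plus cases matching the definition,
# returning also the per-group qualifying-case counts.
apply_case_definition <- function(cohort, case_def) {
  stopifnot(inherits(case_def, "case_definition"))
  qualifies <- case_def$predicate(cohort)
  keep <- (cohort$status == 0) | qualifies
  out <- cohort[keep, , drop = FALSE]
  out
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("case_definition: %s (studies need > %d cases)\n",
              x$label, x$min_cases_per_study))
  invisible(x)
}
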