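#' Derive the evaluation-method columns from raw line data
#'
#' Adds the mapped 3-category diagnosis of every evaluation method to a
#' line-data table: the attending's and site investigator's initial calls,
#' the two individual discharge calls, the adjudicated discharge consensus,
#' the three panelist calls and their panel consensus, and the unanimous
#' diagnosis. These derived columns are what the comparison specs refer to.
#'
#' @param line_data tibble with the raw 4-level call columns
#'   (\code{call_attending}, \code{call_investigator_initial},
#'   \code{call_investigator_discharge_1/2}, \code{call_adjudicator},
#'   \code{call_rpd_1/2/3}), as produced by [generate_cohort()].
#' @return the table with derived category columns appended.
#' @export
derive_evaluations <- function(line_data) {
  d <- line_data
  d$attending_initial <- map_call(d$call_attending)
  d$investigator_initial <- map_call(d$call_investigator_initial)
  d$investigator_discharge_1 <- map_call(d$call_investigator_discharge_1)
  d$investigator_discharge_2 <- map_call(d$call_investigator_discharge_2)
  d$discharge_consensus <- consensus_discharge(
    d$call_investigator_discharge_1, d$call_investigator_discharge_2,
    d$call_adjudicator, patient_id = d$patient_id)
  d$rpd_1 <- map_call(d$call_rpd_1)
  d$rpd_2 <- map_call(d$call_rpd_2)
  d$rpd_3 <- map_call(d$call_rpd_3)
  d$rpd_consensus <- consensus_rpd(d$call_rpd_1, d$call_rpd_2, d$call_rpd_3)
  d$unanimous <- unanimous_diagnosis(d$discharge_consensus, d$rpd_1, d$rpd_2,
                                     d$rpd_3)
  d
}

#' The standard evaluator comparisons A-K
#'
#' The lettered comparison framework between evaluation methods:
#' \tabular{ll}{
#'  A \tab attending initial vs site-investigator initial \cr
#'  B \tab attending initial vs discharge consensus \cr
#'  C \tab attending initial vs external panel (RPD) consensus \cr
#'  D \tab investigator initial vs discharge consensus \cr
#'  E \tab investigator initial vs RPD consensus \cr
#'  F \tab discharge consensus vs RPD consensus \cr
#'  G/H/I \tab the three pairwise panelist comparisons \cr
#'  J \tab the two site investigators' discharge calls \cr
#'  K \tab discharge consensus vs the unanimous diagnosis \cr
#' }
#'
#' @param ids subset of letters to return (default all).
#' @return tibble with columns \code{id}, \code{evaluator_a},
#'   \code{evaluator_b}, \code{description}.
#' @export
comparison_specs <- function(ids = LETTERS[1:11]) {
  specs <- tibble::tribble(
    ~id, ~evaluator_a, ~evaluator_b, ~description,
    "A", "attending_initial", "investigator_initial",
    "initial impressions: attending vs site investigator",
    "B", "attending_initial", "discharge_consensus",
    "attending initial vs local reference (discharge consensus)",
    "C", "attending_initial", "rpd_consensus",
    "attending initial vs external reference (RPD consensus)",
    "D", "investigator_initial", "discharge_consensus",
    "investigator initial vs discharge consensus",
    "E", "investigator_initial", "rpd_consensus",
    "investigator initial vs RPD consensus",
    "F", "discharge_consensus", "rpd_consensus",
    "local vs external reference",
    "G", "rpd_1", "rpd_2", "panelists 1 vs 2",
    "H", "rpd_1", "rpd_3", "panelists 1 vs 3",
    "I", "rpd_2", "rpd_3", "panelists 2 vs 3",
    "J", "investigator_discharge_1", "investigator_discharge_2",
    "site investigators' discharge calls",
    "K", "discharge_consensus", "unanimous",
    "local reference vs unanimous diagnosis"
  )
  specs[specs$id %in% ids, ]
}

#' Map of the fifteen numbered comparisons to letters and cohorts
#'
#' The numbered comparisons 1-15 are five lettered comparisons (A, B, C, E,
#' F) each run on cohort V, cohort Vs, and the pooled V+Vs. Shipped as data
#' so the mapping can be corrected without code change.
#'
#' @return tibble with columns \code{number}, \code{id}, \code{cohort}.
#' @export
numbered_comparison_map <- function() {
  tibble::tibble(
    number = 1:15,
    id = rep(c("A", "B", "C", "E", "F"), each = 3),
    cohort = rep(c("V", "Vs", "V+Vs"), times = 5)
  )
}

filter_cohort <- function(data, cohort) {
  if (is.null(cohort) || identical(cohort, "V+Vs")) return(data)
  data[!is.na(data$cohort_label) & data$cohort_label %in% cohort, ]
}

has_site <- function(infection_sites, site) {
  vapply(strsplit(as.character(infection_sites), ";"),
         function(s) any(s %in% site), logical(1))
}

#' Run one evaluator comparison
#'
#' Builds the two-rater rating matrix for a pair of derived evaluation
#' columns — after optional cohort / hospital / infection-site filtering
#' and pairwise deletion of patients missing either evaluation — and
#' returns its agreement statistics. A stratum with fewer than two
#' complete patients yields a flagged empty result rather than an error.
#'
#' @param line_data a table that carries the derived evaluation columns
#'   (see [derive_evaluations()]; it is applied automatically when the raw
#'   call columns are present but the derived ones are not).
#' @param spec one row of [comparison_specs()] (or a list with
#'   \code{id}, \code{evaluator_a}, \code{evaluator_b}).
#' @param cohort \code{"V"}, \code{"Vs"}, or \code{"V+Vs"} (default: no
#'   filter).
#' @param hospital optional hospital label filter.
#' @param infection_site optional site filter (matches any of a patient's
#'   sites; use \code{"none"} for no identified site).
#' @param ci,level,reps,seed confidence-interval options passed to
#'   [agreement_result()].
#' @return one-row tibble of agreement statistics; column \code{flag} is
#'   \code{"empty stratum"} when there is nothing to compare.
#' @export
run_comparison <- function(line_data, spec, cohort = NULL, hospital = NULL,
                           infection_site = NULL, ci = FALSE, level = 0.95,
                           reps = 2000, seed = NULL) {
  a <- spec$evaluator_a
  b <- spec$evaluator_b
  if (identical(a, b)) {
    stop("a comparison must involve two distinct evaluations", call. = FALSE)
  }
  if (!all(c(a, b) %in% names(line_data)) &&
      "call_attending" %in% names(line_data)) {
    line_data <- derive_evaluations(line_data)
  }
  if (!all(c(a, b) %in% names(line_data))) {
    stop("evaluation column(s) not derivable: ",
         paste(setdiff(c(a, b), names(line_data)), collapse = ", "),
         call. = FALSE)
  }
  d <- filter_cohort(line_data, cohort)
  if (!is.null(hospital)) d <- d[d$hospital %in% hospital, ]
  if (!is.null(infection_site)) d <- d[has_site(d$infection_sites, infection_site), ]
  ca <- as.character(d[[a]])
  cb <- as.character(d[[b]])
  keep <- !is.na(ca) & !is.na(cb)
  n_dropped <- sum(!keep)
  if (sum(keep) < 2) {
    out <- tibble::tibble(
      comparison_id = spec$id, N = sum(keep), n_raters = 2L, k = 3L,
      p_o = NA_real_, p_e_free = NA_real_, p_e_fixed = NA_real_,
      kappa_free = NA_real_, kappa_fixed = NA_real_,
      kappa_fixed_undefined = NA, flag = "empty stratum")
    out$n_dropped <- n_dropped
    return(out)
  }
  m <- rating_matrix(cbind(ca[keep], cb[keep]), categories = category_levels())
  out <- agreement_result(m, comparison_id = spec$id, ci = ci, level = level,
                          reps = reps, seed = seed)
  out$flag <- NA_character_
  out$n_dropped <- n_dropped
  out
}

#' Run a set of comparisons across cohorts
#'
#' One [run_comparison()] per spec per cohort filter; the row layout of
#' the standard agreement report (overall agreement, free- and
#' fixed-marginal kappa per comparison).
#'
#' @param line_data line-data table.
#' @param specs tibble of comparison specs (default all of A-K).
#' @param cohorts cohort filters (default pooled only).
#' @param ... passed to [run_comparison()].
#' @return tibble with one row per spec x cohort, including a
#'   \code{cohort} column.
#' @export
run_all <- function(line_data, specs = comparison_specs(),
                    cohorts = "V+Vs", ...) {
  if (!all(c(specs$evaluator_a, specs$evaluator_b) %in% names(line_data)) &&
      "call_attending" %in% names(line_data)) {
    line_data <- derive_evaluations(line_data)
  }
  rows <- list()
  for (co in cohorts) {
    for (i in seq_len(nrow(specs))) {
      r <- run_comparison(line_data, specs[i, ], cohort = co, ...)
      r$cohort <- co
      rows[[length(rows) + 1L]] <- r
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-patient indeterminate vote fraction
#'
#' The fraction of a patient's evaluation methods that call the case
#' indeterminate — an auxiliary per-patient uncertainty statistic. The
#' composition is configurable; the default uses the five method-level
#' evaluations (attending initial, investigator initial, discharge
#' consensus, RPD consensus, unanimous).
#'
#' @param line_data table with derived evaluation columns (derived
#'   automatically from raw calls when needed).
#' @param evaluations character vector of evaluation columns to pool.
#' @return numeric vector of fractions in \[0, 1\] (NA evaluations are
#'   excluded from a patient's denominator).
#' @export
indeterminate_vote_fraction <- function(line_data,
                                        evaluations = c("attending_initial",
                                                        "investigator_initial",
                                                        "discharge_consensus",
                                                        "rpd_consensus",
                                                        "unanimous")) {
  if (!all(evaluations %in% names(line_data)) &&
      "call_attending" %in% names(line_data)) {
    line_data <- derive_evaluations(line_data)
  }
  m <- sapply(evaluations, function(cl) {
    as.character(line_data[[cl]]) == "indeterminate"
  })
  m <- matrix(m, nrow = nrow(line_data))
  rowMeans(m, na.rm = TRUE)
}
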