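#' Diagnostic call and category vocabularies
#'
#' Evaluators make a 4-level infection call: \code{none}, \code{possible},
#' \code{probable}, or \code{definite}. All agreement analysis is carried out
#' on the mapped 3-category diagnosis scale \code{SIRS} <
#' \code{indeterminate} < \code{sepsis} (ordered by apparent risk).
#'
#' @return character vector of the canonical levels, in order.
#' @export
call_levels <- function() c("none", "possible", "probable", "definite")

#' @rdname call_levels
#' @export
category_levels <- function() c("SIRS", "indeterminate", "sepsis")

#' Parse 4-level infection calls
#'
#' Case-insensitive parse into the closed vocabulary; unknown tokens are an
#' error naming the token and its row. \code{NA} passes through (a missing
#' call).
#'
#' @param x character or factor vector of calls.
#' @return factor with levels \code{call_levels()}.
#' @export
parse_call <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  x0 <- tolower(trimws(as.character(x)))
  x0[!nzchar(x0)] <- NA_character_
  bad <- !is.na(x0) & !(x0 %in% call_levels())
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown diagnostic call '%s' (row %d)", x0[i], i),
         call. = FALSE)
  }
  factor(x0, levels = call_levels())
}

#' Parse 3-category diagnoses
#'
#' @param x character or factor vector of categories (case-insensitive;
#'   "sirs" is canonicalised to "SIRS").
#' @return factor with levels \code{category_levels()}.
#' @export
parse_category <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  x0 <- tolower(trimws(as.character(x)))
  x0[!nzchar(x0)] <- NA_character_
  canon <- setNames(category_levels(), tolower(category_levels()))
  bad <- !is.na(x0) & !(x0 %in% names(canon))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown diagnosis category '%s' (row %d)", x0[i], i),
         call. = FALSE)
  }
  factor(unname(canon[x0]), levels = category_levels())
}

#' Map a 4-level infection call to its 3-category diagnosis
#'
#' \code{none} maps to SIRS, \code{possible} to indeterminate, and both
#' \code{probable} and \code{definite} to sepsis. Agreement between
#' evaluators is judged on this mapped scale throughout the package, so a
#' probable-vs-definite split counts as agreement on sepsis.
#'
#' @param call vector of calls (parsed with [parse_call()]).
#' @return factor of categories with levels \code{category_levels()}.
#' @examples
#' map_call(c("none", "possible", "probable", "definite"))
#' @export
map_call <- function(call) {
  call <- parse_call(call)
  map <- c(none = "SIRS", possible = "indeterminate",
           probable = "sepsis", definite = "sepsis")
  factor(unname(map[as.character(call)]), levels = category_levels())
}

# Majority vote of three mapped categories; all-distinct -> indeterminate.
majority3 <- function(c1, c2, c3) {
  out <- rep(NA_character_, length(c1))
  c1 <- as.character(c1); c2 <- as.character(c2); c3 <- as.character(c3)
  out[c1 == c2 | c1 == c3] <- c1[c1 == c2 | c1 == c3]
  out[c2 == c3 & c1 != c2] <- c2[c2 == c3 & c1 != c2]
  out[c1 != c2 & c1 != c3 & c2 != c3] <- "indeterminate"
  factor(out, levels = category_levels())
}

#' Consensus discharge diagnosis of the two site investigators
#'
#' The two site investigators review the chart independently at discharge.
#' If their mapped categories agree, that category is the consensus. A
#' disagreement triggers review by a third, equally qualified adjudicator:
#' the consensus is then the majority of the three mapped categories, and a
#' three-way disagreement (or "possible" from all three) is classified as
#' indeterminate.
#'
#' @param inv1,inv2 4-level calls of the two site investigators.
#' @param adjudicator 4-level call of the adjudicator; may be \code{NA} for
#'   patients whose investigators agree, but must be present whenever their
#'   mapped categories differ.
#' @param patient_id optional ids used in the adjudication-required error.
#' @return factor of consensus categories.
#' @export
consensus_discharge <- function(inv1, inv2, adjudicator = NULL,
                                patient_id = NULL) {
  c1 <- map_call(inv1)
  c2 <- map_call(inv2)
  n <- length(c1)
  if (is.null(adjudicator)) adjudicator <- rep(NA_character_, n)
  c3 <- map_call(adjudicator)
  need <- !is.na(c1) & !is.na(c2) & c1 != c2
  if (any(need & is.na(c3))) {
    i <- which(need & is.na(c3))[1L]
    id <- if (is.null(patient_id)) as.character(i) else as.character(patient_id[i])
    stop(sprintf("adjudication required for patient %s: site investigators disagree and no adjudicator call is present", id),
         call. = FALSE)
  }
  out <- c1
  out[need] <- majority3(c1[need], c2[need], c3[need])
  out[is.na(c1) | is.na(c2)] <- NA
  out
}

#' Consensus diagnosis of the three-member external expert panel (RPD)
#'
#' Each retrospective physician diagnosis (RPD) panelist makes a 4-level
#' call; calls are mapped to categories and the panel consensus is the
#' category chosen by at least two of the three panelists. If all three
#' mapped categories differ, the consensus is indeterminate.
#'
#' @param p1,p2,p3 4-level calls of the three panelists.
#' @return factor of consensus categories.
#' @export
consensus_rpd <- function(p1, p2, p3) {
  c1 <- map_call(p1); c2 <- map_call(p2); c3 <- map_call(p3)
  out <- majority3(c1, c2, c3)
  out[is.na(c1) | is.na(c2) | is.na(c3)] <- NA
  out
}

#' Unanimous diagnosis across discharge consensus and all three panelists
#'
#' The highest-certainty evaluation: SIRS (or sepsis) only when the site
#' investigators' consensus discharge category and all three individual
#' panelist categories are identical and equal to SIRS (or sepsis). Anything
#' less than unanimous — including four-way agreement on indeterminate — is
#' indeterminate.
#'
#' @param discharge,p1,p2,p3 3-category diagnoses
#'   (parsed with [parse_category()]).
#' @return factor of categories.
#' @export
unanimous_diagnosis <- function(discharge, p1, p2, p3) {
  d <- parse_category(discharge)
  c1 <- parse_category(p1); c2 <- parse_category(p2); c3 <- parse_category(p3)
  all_eq <- d == c1 & d == c2 & d == c3
  out <- factor(rep("indeterminate", length(d)), levels = category_levels())
  firm <- !is.na(all_eq) & all_eq & d %in% c("SIRS", "sepsis")
  out[firm] <- d[firm]
  out[is.na(d) | is.na(c1) | is.na(c2) | is.na(c3)] <- NA
  out
}
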