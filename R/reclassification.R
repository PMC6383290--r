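#' Reclassification (risk-transition) summary between two evaluations
#'
#' Cross-tabulates an initial against a later 3-category diagnosis and
#' summarizes the six off-diagonal transitions, each labelled with its
#' change in apparent risk on the SIRS < indeterminate < sepsis ordering:
#' moves toward sepsis are risk increases (a patient initially read as
#' non-infected who proves septic risks delayed antibiotics), moves toward
#' SIRS are decreases (excess antibiotic use).
#'
#' @param line_data table with derived evaluation columns (derived
#'   automatically from raw calls when needed).
#' @param initial_col,final_col names of the initial and final category
#'   columns (e.g. \code{"attending_initial"}, \code{"discharge_consensus"}).
#' @return object of class \code{reclassification_summary}: a list with the
#'   3 x 3 \code{table}, a \code{transitions} tibble (from, to, count,
#'   percent, risk_direction), \code{total} reclassified, \code{N}, and
#'   \code{percent_total} (of N, in percent).
#' @export
reclassification_table <- function(line_data, initial_col, final_col) {
  if (!all(c(initial_col, final_col) %in% names(line_data)) &&
      "call_attending" %in% names(line_data)) {
    line_data <- derive_evaluations(line_data)
  }
  ini <- parse_category(line_data[[initial_col]])
  fin <- parse_category(line_data[[final_col]])
  keep <- !is.na(ini) & !is.na(fin)
  ini <- ini[keep]; fin <- fin[keep]
  N <- length(ini)
  tab <- table(initial = ini, final = fin)

  lv <- category_levels()
  risk_rank <- setNames(seq_along(lv), lv)
  trans <- expand.grid(from = lv, to = lv, stringsAsFactors = FALSE)
  trans <- trans[trans$from != trans$to, ]
  # report in risk-impact order: increases first, largest jumps first
  ord <- order(-(risk_rank[trans$to] - risk_rank[trans$from]),
               risk_rank[trans$from])
  trans <- trans[ord, ]
  trans$count <- mapply(function(f, t) tab[f, t], trans$from, trans$to)
  trans$percent <- 100 * trans$count / N
  trans$risk_direction <- ifelse(risk_rank[trans$to] > risk_rank[trans$from],
                                 "increase", "decrease")
  trans <- tibble::as_tibble(trans)
  total <- sum(trans$count)
  structure(
    list(table = tab, transitions = trans, total = total, N = N,
         percent_total = 100 * total / N,
         initial_col = initial_col, final_col = final_col),
    class = "reclassification_summary")
}

#' @export
print.reclassification_summary <- function(x, ...) {
  cat(sprintf("reclassification %s -> %s (N = %d)\n",
              x$initial_col, x$final_col, x$N))
  tr <- x$transitions
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %-13s -> %-13s %3d (%.1f%%)  risk %s\n",
                tr$from[i], tr$to[i], tr$count[i],
                round_half_up(tr$percent[i], 1), tr$risk_direction[i]))
  }
  cat(sprintf("  total reclassified: %d (%.1f%%)\n",
              x$total, round_half_up(x$percent_total, 1)))
  invisible(x)
}
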