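#' Build a rating matrix from categorical calls or category counts
#'
#' The container for agreement statistics: N items (patients) rated by n
#' raters into k categories, stored as an N x k matrix of counts
#' \eqn{n_{ij}} (number of raters assigning item i to category j). When
#' built from raw calls the item x rater call matrix is retained, which
#' allows Cohen's kappa (rater-specific marginals) for two raters; a
#' counts-only matrix supports the pooled (Fleiss) fixed-marginal kappa.
#'
#' @param calls an N x n matrix or data.frame of categorical calls (no
#'   missing values; filter items first).
#' @param counts an N x k integer matrix of category counts with constant
#'   row sums; ignored when \code{calls} is given.
#' @param categories category labels; defaults to the sorted values present
#'   (for calls) or the column names (for counts). Pass
#'   [category_levels()] to fix k = 3 even if a category is unused.
#' @return an object of class \code{rating_matrix} with elements
#'   \code{counts}, \code{calls} (or NULL), \code{N}, \code{n}, \code{k},
#'   \code{categories}.
#' @examples
#' m <- rating_matrix(cbind(c("SIRS", "sepsis"), c("SIRS", "sepsis")),
#'                    categories = category_levels())
#' overall_agreement(m)
#' @export
rating_matrix <- function(calls = NULL, counts = NULL, categories = NULL) {
  if (!is.null(calls)) {
    calls <- as.matrix(as.data.frame(lapply(as.data.frame(calls), as.character),
                                     stringsAsFactors = FALSE))
    if (ncol(calls) < 2) stop("at least two raters required", call. = FALSE)
    if (anyNA(calls)) stop("missing calls in rating matrix; drop incomplete items first", call. = FALSE)
    if (is.null(categories)) categories <- sort(unique(as.vector(calls)))
    if (!all(as.vector(calls) %in% categories)) {
      stop("calls outside the stated category set", call. = FALSE)
    }
    counts <- vapply(categories, function(l) rowSums(calls == l),
                     numeric(nrow(calls)))
    counts <- matrix(counts, nrow = nrow(calls),
                     dimnames = list(NULL, categories))
  } else {
    if (is.null(counts)) stop("supply calls or counts", call. = FALSE)
    counts <- as.matrix(counts)
    if (is.null(categories)) {
      categories <- colnames(counts)
      if (is.null(categories)) categories <- paste0("cat", seq_len(ncol(counts)))
    }
    colnames(counts) <- categories
    calls <- NULL
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1L) {
    stop("every item must be rated by the same number of raters", call. = FALSE)
  }
  n <- unique(rs)
  if (ncol(counts) < 2) stop("at least two categories required", call. = FALSE)
  structure(
    list(counts = counts, calls = calls, N = nrow(counts), n = n,
         k = ncol(counts), categories = categories),
    class = "rating_matrix"
  )
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("rating matrix: %d items x %d raters, %d categories (%s)\n",
              x$N, x$n, x$k, paste(x$categories, collapse = ", ")))
  invisible(x)
}

# subset items (used by the bootstrap)
rm_subset <- function(m, idx) {
  rating_matrix(
    calls = if (!is.null(m$calls)) m$calls[idx, , drop = FALSE] else NULL,
    counts = if (is.null(m$calls)) m$counts[idx, , drop = FALSE] else NULL,
    categories = m$categories
  )
}
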