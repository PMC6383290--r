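#' ROC area under the curve (Mann-Whitney rank form)
#'
#' AUC computed as the normalized Mann-Whitney U statistic: the proportion
#' of (positive, negative) score pairs in which the positive scores higher,
#' with ties credited 0.5. Equivalent to the trapezoidal area under the
#' empirical ROC curve. The confidence interval is a stratified percentile
#' bootstrap (cases and controls resampled separately).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or two-level factor whose
#'   second sorted level is "positive").
#' @param ci compute the bootstrap interval?
#' @param level confidence level.
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return one-row tibble: \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{n_pos}, \code{n_neg}.
#' @examples
#' roc_auc(c(0.9, 0.6, 0.7, 0.4), c(TRUE, TRUE, FALSE, FALSE), ci = FALSE)
#' @export
roc_auc <- function(scores, labels, ci = TRUE, level = 0.95, reps = 2000,
                    seed = NULL) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels[!is.na(labels)])))
    if (length(lv) != 2) stop("labels must be binary", call. = FALSE)
    labels <- as.character(labels) == lv[2]
  }
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  auc_rank <- function(s, l) {
    r <- rank(s)
    np <- sum(l)
    (sum(r[l]) - np * (np + 1) / 2) / (np * sum(!l))
  }
  auc <- auc_rank(scores, labels)
  lo <- hi <- NA_real_
  if (ci) {
    pos <- scores[labels]; neg <- scores[!labels]
    alpha <- (1 - level) / 2
    qs <- with_seed(seed, {
      stats_b <- vapply(seq_len(reps), function(b) {
        sp <- sample(pos, n_pos, replace = TRUE)
        sn <- sample(neg, n_neg, replace = TRUE)
        auc_rank(c(sp, sn), c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
      }, numeric(1))
      quantile(stats_b, c(alpha, 1 - alpha), names = FALSE)
    })
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(auc = auc, ci_low = lo, ci_high = hi,
                 n_pos = n_pos, n_neg = n_neg)
}
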