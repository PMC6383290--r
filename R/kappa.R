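#' Overall percent agreement
#'
#' The fraction of agreeing rater pairs, averaged over items:
#' \deqn{P_o = \frac{1}{N} \sum_i \frac{\sum_j n_{ij}(n_{ij}-1)}{n(n-1)}.}
#' For two raters this is simply the fraction of items on which both raters
#' assign the same category.
#'
#' @param m a [rating_matrix()].
#' @return observed agreement proportion in \[0, 1\].
#' @export
overall_agreement <- function(m) {
  stopifnot(inherits(m, "rating_matrix"))
  if (m$n < 2) stop("at least two raters required", call. = FALSE)
  a <- rowSums(m$counts * (m$counts - 1)) / (m$n * (m$n - 1))
  mean(a)
}

#' Free-marginal (Randolph) multirater kappa
#'
#' Chance-corrected agreement under the free-marginal assumption that each
#' of the k categories is a priori equally likely, so chance agreement is
#' \eqn{P_e = 1/k}:
#' \deqn{\kappa_{free} = \frac{P_o - 1/k}{1 - 1/k}.}
#' For k = 3 this reduces to \eqn{(3 P_o - 1)/2}. Appropriate when raters
#' are not constrained to reproduce fixed category marginals, and stable in
#' small strata where marginal estimates are noisy.
#'
#' @param m a [rating_matrix()].
#' @return the kappa statistic (full precision; see [round_half_up()] for
#'   the 2-decimal text convention).
#' @export
kappa_free <- function(m) {
  kappa_free_from_agreement(overall_agreement(m), m$k)
}

#' @rdname kappa_free
#' @param p_o observed overall agreement proportion.
#' @param k number of categories (>= 2).
#' @export
kappa_free_from_agreement <- function(p_o, k = 3) {
  if (k < 2) stop("at least two categories required", call. = FALSE)
  stopifnot(all(p_o >= 0 & p_o <= 1))
  (p_o - 1 / k) / (1 - 1 / k)
}

#' Fixed-marginal kappa (Cohen for two raters, Fleiss for more)
#'
#' Chance-corrected agreement with chance computed from the observed
#' category marginals. For two raters with the raw calls available, Cohen's
#' kappa is used: \eqn{p_e = \sum_j r_j c_j} with \eqn{r_j, c_j} the two
#' raters' marginal proportions. Otherwise the pooled-marginal (Fleiss)
#' form is used: \eqn{P_e = \sum_j p_j^2} with \eqn{p_j} the pooled
#' proportion of all ratings in category j. Since \eqn{\sum_j p_j^2 \ge
#' 1/k}, the pooled fixed-marginal kappa never exceeds the free-marginal
#' kappa, and falls increasingly below it as the marginals grow skewed.
#'
#' When the marginals are degenerate (\eqn{p_e = 1}: every rating in one
#' category) the statistic is undefined; \code{NA} is returned with
#' attribute \code{undefined = TRUE}.
#'
#' @param m a [rating_matrix()].
#' @param method \code{"auto"} (Cohen when n = 2 and calls are stored, else
#'   Fleiss), \code{"cohen"}, or \code{"fleiss"}.
#' @return the kappa statistic, or flagged \code{NA} when undefined.
#' @export
kappa_fixed <- function(m, method = c("auto", "cohen", "fleiss")) {
  stopifnot(inherits(m, "rating_matrix"))
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (m$n == 2 && !is.null(m$calls)) "cohen" else "fleiss"
  }
  p_o <- overall_agreement(m)
  if (method == "cohen") {
    if (m$n != 2 || is.null(m$calls)) {
      stop("Cohen's kappa needs the raw calls of exactly two raters", call. = FALSE)
    }
    r <- table(factor(m$calls[, 1], levels = m$categories)) / m$N
    c_ <- table(factor(m$calls[, 2], levels = m$categories)) / m$N
    p_e <- sum(as.numeric(r) * as.numeric(c_))
  } else {
    p_j <- colSums(m$counts) / (m$N * m$n)
    p_e <- sum(p_j^2)
  }
  if (p_e >= 1 - 1e-12) {
    return(structure(NA_real_, undefined = TRUE, p_e = p_e))
  }
  (p_o - p_e) / (1 - p_e)
}

#' Bootstrap confidence interval for a kappa statistic
#'
#' Percentile bootstrap over items (patients): item rows are resampled with
#' replacement and the kappa recomputed on each replicate. Replicates on
#' which the fixed-marginal kappa is undefined are skipped and counted. An
#' analytic normal interval based on the per-item agreement components is
#' available for the free-marginal kappa.
#'
#' @param m a [rating_matrix()].
#' @param which \code{"free"} or \code{"fixed"}.
#' @param level confidence level (default 0.95).
#' @param reps bootstrap replicates (>= 200; default 2000).
#' @param seed integer seed for reproducible resampling.
#' @param method \code{"bootstrap"} (default) or \code{"analytic"}
#'   (free-marginal only).
#' @return list with \code{estimate}, \code{low}, \code{high},
#'   \code{level}, \code{n_skipped}.
#' @export
kappa_ci <- function(m, which = c("free", "fixed"), level = 0.95,
                     reps = 2000, seed = NULL,
                     method = c("bootstrap", "analytic")) {
  stopifnot(inherits(m, "rating_matrix"))
  which <- match.arg(which)
  method <- match.arg(method)
  est <- if (which == "free") kappa_free(m) else as.numeric(kappa_fixed(m))
  alpha <- (1 - level) / 2
  a <- rowSums(m$counts * (m$counts - 1)) / (m$n * (m$n - 1))

  if (method == "analytic") {
    if (which != "free") stop("analytic interval implemented for the free-marginal kappa only", call. = FALSE)
    se <- sd(a) / sqrt(m$N) * m$k / (m$k - 1)
    z <- qnorm(1 - alpha)
    return(list(estimate = est, low = est - z * se, high = est + z * se,
                level = level, n_skipped = 0L))
  }

  if (reps < 200) stop("at least 200 bootstrap replicates required", call. = FALSE)
  with_seed(seed, {
    if (which == "free") {
      # kappa_free is a fixed affine map of mean per-item agreement, so the
      # bootstrap reduces to resampling the agreement components.
      idx <- matrix(sample.int(m$N, m$N * reps, replace = TRUE), nrow = m$N)
      p_o_star <- colMeans(matrix(a[idx], nrow = m$N))
      kap <- kappa_free_from_agreement(p_o_star, m$k)
      n_skip <- 0L
    } else {
      kap <- numeric(reps)
      skip <- logical(reps)
      for (b in seq_len(reps)) {
        idx <- sample.int(m$N, m$N, replace = TRUE)
        kb <- kappa_fixed(rm_subset(m, idx))
        skip[b] <- isTRUE(attr(kb, "undefined"))
        kap[b] <- as.numeric(kb)
      }
      n_skip <- sum(skip)
      kap <- kap[!skip]
    }
    qs <- quantile(kap, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
    list(estimate = est, low = qs[1], high = qs[2], level = level,
         n_skipped = n_skip)
  })
}

#' Sample-size profile of the free/fixed kappa ratio
#'
#' Simulates two-rater rating matrices at a range of sample sizes and
#' reports the mean ratio \eqn{\kappa_{free}/\kappa_{fixed}} (pooled
#' fixed-marginal form). Items are generated from a latent category drawn
#' from \code{marginals}; with probability \code{agreement} both raters
#' report the latent category, otherwise each reports an independent draw
#' from \code{marginals}. With uniform marginals the two statistics
#' coincide (ratio 1); skewed marginals inflate chance agreement under the
#' fixed-marginal model and push the ratio above 1, the more so the smaller
#' and more skewed the sample.
#'
#' @param marginals probability vector over categories (sums to 1).
#' @param agreement probability that the raters deterministically agree on
#'   the latent category.
#' @param sample_sizes integer vector of N values (each >= 10).
#' @param nsim simulated matrices per sample size.
#' @param seed integer seed.
#' @return tibble with columns \code{N}, \code{mean_ratio},
#'   \code{mean_kappa_free}, \code{mean_kappa_fixed}.
#' @export
kappa_ratio_profile <- function(marginals, agreement = 0.7,
                                sample_sizes = c(10, 25, 50, 100, 250),
                                nsim = 100, seed = 1) {
  stopifnot(abs(sum(marginals) - 1) < 1e-8, all(sample_sizes >= 10))
  k <- length(marginals)
  cats <- if (!is.null(names(marginals))) names(marginals) else paste0("cat", seq_len(k))
  with_seed(seed, {
    rows <- lapply(sample_sizes, function(N) {
      kf <- kx <- numeric(nsim)
      for (s in seq_len(nsim)) {
        latent <- sample.int(k, N, replace = TRUE, prob = marginals)
        agree <- runif(N) < agreement
        r1 <- ifelse(agree, latent, sample.int(k, N, replace = TRUE, prob = marginals))
        r2 <- ifelse(agree, latent, sample.int(k, N, replace = TRUE, prob = marginals))
        m <- rating_matrix(cbind(cats[r1], cats[r2]), categories = cats)
        kf[s] <- kappa_free(m)
        kx[s] <- as.numeric(kappa_fixed(m, method = "fleiss"))
      }
      ok <- is.finite(kx) & abs(kx) > 1e-12
      tibble::tibble(N = N,
                     mean_ratio = mean(kf[ok] / kx[ok]),
                     mean_kappa_free = mean(kf),
                     mean_kappa_fixed = mean(kx, na.rm = TRUE))
    })
    dplyr::bind_rows(rows)
  })
}

#' Agreement statistics for one comparison
#'
#' Bundles observed agreement, both kappa variants, and (optionally)
#' bootstrap confidence intervals into a one-row tibble, the unit of the
#' comparison pipeline's report.
#'
#' @param m a [rating_matrix()].
#' @param comparison_id identifier carried into the report.
#' @param ci compute bootstrap confidence intervals?
#' @param level,reps,seed passed to [kappa_ci()].
#' @return one-row tibble with columns \code{comparison_id}, \code{N},
#'   \code{n_raters}, \code{k}, \code{p_o}, \code{p_e_free},
#'   \code{p_e_fixed}, \code{kappa_free}, \code{kappa_fixed},
#'   \code{kappa_fixed_undefined} and, when \code{ci}, the interval bounds.
#' @export
agreement_result <- function(m, comparison_id = NA_character_, ci = FALSE,
                             level = 0.95, reps = 2000, seed = NULL) {
  p_o <- overall_agreement(m)
  kf <- kappa_free(m)
  kx <- kappa_fixed(m)
  p_j <- colSums(m$counts) / (m$N * m$n)
  out <- tibble::tibble(
    comparison_id = comparison_id,
    N = m$N, n_raters = m$n, k = m$k,
    p_o = p_o, p_e_free = 1 / m$k, p_e_fixed = sum(p_j^2),
    kappa_free = kf, kappa_fixed = as.numeric(kx),
    kappa_fixed_undefined = isTRUE(attr(kx, "undefined"))
  )
  if (ci) {
    ci_f <- kappa_ci(m, "free", level = level, reps = reps, seed = seed)
    out$kappa_free_ci_low <- ci_f$low
    out$kappa_free_ci_high <- ci_f$high
    if (!out$kappa_fixed_undefined) {
      ci_x <- kappa_ci(m, "fixed", level = level, reps = reps, seed = seed)
      out$kappa_fixed_ci_low <- ci_x$low
      out$kappa_fixed_ci_high <- ci_x$high
    } else {
      out$kappa_fixed_ci_low <- NA_real_
      out$kappa_fixed_ci_high <- NA_real_
    }
  }
  out
}
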