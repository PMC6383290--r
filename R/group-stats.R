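group_result <- function(test_name, statistic, p_value, n1, n2, detail = NA_real_,
                         flag = NA_character_) {
  tibble::tibble(test_name = test_name, statistic = statistic,
                 p_value = p_value, n1 = n1, n2 = n2, detail = detail,
                 flag = flag)
}

#' Two-proportion z-test (pooled variance, no continuity correction)
#'
#' Tests equality of two binomial proportions with the pooled-variance z
#' statistic \eqn{z = (\hat p_1 - \hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1 +
#' 1/n_2)}} and a two-tailed normal p-value. No continuity correction is
#' applied; \eqn{z^2} equals the uncorrected Pearson chi-square of the
#' equivalent 2x2 table. A warning is issued in the small-expected-count
#' regime (\eqn{n \hat p < 5}) where [n1_chi_square()] is preferred.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return one-row tibble (see \code{GroupTestResult} fields: test,
#'   statistic, two-tailed p, group sizes, pooled proportion in
#'   \code{detail}).
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p_pool <- (x1 + x2) / (n1 + n2)
  if (min(n1, n2) * p_pool < 5 || min(n1, n2) * (1 - p_pool) < 5) {
    warning("expected counts below 5; consider n1_chi_square()", call. = FALSE)
  }
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (x1 / n1 - x2 / n2) / se
  p <- 2 * pnorm(-abs(z))
  group_result("two_proportion_z", z, p, n1, n2, detail = p_pool)
}

#' N-1 chi-square test for two proportions
#'
#' The uncorrected Pearson chi-square of the 2x2 table scaled by
#' \eqn{(N-1)/N}, recommended over the plain chi-square when expected
#' counts are small. Two-tailed p from the chi-square distribution with one
#' degree of freedom. A table with a zero margin leaves the statistic
#' undefined (flagged \code{NA}).
#'
#' @inheritParams two_proportion_z
#' @return one-row tibble; \code{detail} holds the unscaled Pearson
#'   chi-square.
#' @export
n1_chi_square <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  N <- n1 + n2
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(group_result("n1_chi_square", NA_real_, NA_real_, n1, n2,
                        flag = "zero-margin table; statistic undefined"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- sum((tab - expected)^2 / expected)
  stat <- chi2 * (N - 1) / N
  group_result("n1_chi_square", stat, pchisq(stat, df = 1, lower.tail = FALSE),
               n1, n2, detail = chi2)
}

#' Two-tailed pooled-variance t-test
#'
#' Classic two-sample Student t-test assuming equal variances, applied to
#' available cases (missing values dropped per sample, no imputation). Used
#' by the parameter screens contrasting patient strata on continuous
#' covariates.
#'
#' @param sample1,sample2 numeric vectors (NA allowed; dropped).
#' @return one-row tibble; \code{detail} holds the degrees of freedom.
#' @export
t_test_equal_var <- function(sample1, sample2) {
  s1 <- sample1[!is.na(sample1)]
  s2 <- sample2[!is.na(sample2)]
  if (length(s1) < 2 || length(s2) < 2) {
    stop("each sample needs at least two non-missing values", call. = FALSE)
  }
  if (var(s1) == 0 && var(s2) == 0) {
    flag <- if (mean(s1) == mean(s2)) NA_character_ else "zero pooled variance"
    stat <- if (mean(s1) == mean(s2)) 0 else NA_real_
    p <- if (mean(s1) == mean(s2)) 1 else NA_real_
    return(group_result("t_test_equal_var", stat, p, length(s1), length(s2),
                        detail = length(s1) + length(s2) - 2, flag = flag))
  }
  tt <- t.test(s1, s2, var.equal = TRUE)
  group_result("t_test_equal_var", unname(tt$statistic), tt$p.value,
               length(s1), length(s2), detail = unname(tt$parameter))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between the two empirical CDFs with the asymptotic
#' two-tailed p-value; used to contrast whole distributions of agreement
#' statistics between strata.
#'
#' @param sample1,sample2 numeric vectors (NA dropped).
#' @return one-row tibble with the D statistic.
#' @export
ks_two_sample <- function(sample1, sample2) {
  s1 <- sample1[!is.na(sample1)]
  s2 <- sample2[!is.na(sample2)]
  if (length(s1) < 2 || length(s2) < 2) {
    stop("each sample needs at least two non-missing values", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(s1, s2))
  group_result("ks_two_sample", unname(kt$statistic), kt$p.value,
               length(s1), length(s2))
}

#' Screen clinical parameters for association with a binary grouping
#'
#' For each parameter, contrasts the two groups with a pooled-variance
#' t-test (continuous parameters) or a two-proportion z-test (binary /
#' two-level parameters), on available cases per parameter (no imputation),
#' and returns the table sorted by increasing p-value — the format of the
#' treated-vs-untreated SIRS screen. No multiple-testing correction is
#' applied by default; set \code{adjust = "BH"} for Benjamini-Hochberg
#' adjusted p-values in an extra column.
#'
#' @param data data frame of patient records.
#' @param group name of a binary grouping column (logical or two-level).
#' @param parameters character vector of parameter column names.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return tibble with one row per screened parameter: test used, group
#'   Ns, statistic, p-value, sorted by ascending p; all-missing parameters
#'   are excluded (attribute \code{excluded} lists them).
#' @export
parameter_screen <- function(data, group, parameters, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g <- data[[group]]
  if (is.factor(g) || is.character(g)) {
    lv <- sort(unique(as.character(g[!is.na(g)])))
    if (length(lv) != 2) stop("grouping must be binary", call. = FALSE)
    g <- as.character(g) == lv[2]
  }
  g <- as.logical(g)
  excluded <- character(0)
  rows <- list()
  for (p in parameters) {
    v <- data[[p]]
    keep <- !is.na(v) & !is.na(g)
    if (!any(keep)) {
      excluded <- c(excluded, p)
      next
    }
    vv <- v[keep]; gg <- g[keep]
    is_binary <- is.logical(vv) || is.factor(vv) || is.character(vv) ||
      length(unique(vv)) <= 2
    res <- tryCatch({
      if (is_binary) {
        if (is.factor(vv) || is.character(vv)) {
          lv <- sort(unique(as.character(vv)))
          vv <- as.character(vv) == lv[length(lv)]
        }
        vv <- as.logical(vv)
        suppressWarnings(
          two_proportion_z(sum(vv[gg]), sum(gg), sum(vv[!gg]), sum(!gg))
        )
      } else {
        t_test_equal_var(vv[gg], vv[!gg])
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      excluded <- c(excluded, p)
      next
    }
    res$parameter <- p
    rows[[p]] <- res
  }
  if (!length(rows)) stop("no screenable parameters", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  out <- out[, c("parameter", setdiff(names(out), "parameter"))]
  out <- out[order(out$p_value), ]
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  attr(out, "excluded") <- excluded
  out
}

#' Three-group ANOVA p-value (thin pass-through)
#'
#' Convenience wrapper around \code{aov} for three-way cohort-description
#' contrasts of continuous covariates.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return the ANOVA F-test p-value.
#' @export
group_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  fit <- aov(values[keep] ~ factor(groups[keep]))
  summary(fit)[[1]][["Pr(>F)"]][1]
}
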