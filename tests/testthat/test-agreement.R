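test_that("overall agreement matches hand-enumerated pair counts", {
  # two raters, 49 items, 33 exact matches
  a <- rep(c("SIRS", "sepsis", "indeterminate"), length.out = 49)
  b <- a
  b[1:16] <- ifelse(a[1:16] == "SIRS", "sepsis", "SIRS")
  m <- rm2(a, b)
  expect_equal(overall_agreement(m), 33 / 49)
  # three raters, items (A,A,B) and (A,A,A): (1/3 + 1)/2
  m3 <- rating_matrix(rbind(c("A", "A", "B"), c("A", "A", "A")),
                      categories = c("A", "B"))
  expect_equal(overall_agreement(m3), 2 / 3)
  # perfect agreement
  mp <- rm2(a, a)
  expect_equal(overall_agreement(mp), 1)
  one_rater <- matrix(c(1, 0, 0), nrow = 4, ncol = 3, byrow = TRUE)
  expect_error(overall_agreement(rating_matrix(counts = one_rater)),
               "at least two raters")
})

test_that("free-marginal kappa is the stated affine map of agreement", {
  expect_equal(round_half_up(kappa_free_from_agreement(33 / 49, 3)), 0.51)
  expect_equal(kappa_free_from_agreement(1, 5), 1)
  expect_equal(kappa_free_from_agreement(1 / 3, 3), 0)
  # linear in P_o with slope k/(k-1), on a grid
  po <- seq(0, 1, by = 0.05)
  for (k in 2:5) {
    kf <- kappa_free_from_agreement(po, k)
    expect_equal(diff(kf) / diff(po), rep(k / (k - 1), length(po) - 1))
  }
  expect_error(kappa_free_from_agreement(0.5, 1), "at least two categories")
})

test_that("Cohen's kappa reproduces the hand-computed 2x2 example", {
  # cross-table [[20,5],[10,15]]: p_o = 0.70, p_e = 0.50, kappa = 0.40
  a <- c(rep("X", 25), rep("Y", 25))
  b <- c(rep("X", 20), rep("Y", 5), rep("X", 10), rep("Y", 15))
  m <- rating_matrix(cbind(a, b), categories = c("X", "Y"))
  expect_equal(kappa_fixed(m, method = "cohen"), 0.4)
  expect_equal(kappa_fixed(m, method = "cohen"), oracle_cohen(cbind(a, b), c("X", "Y")))
})

test_that("degenerate marginals flag the fixed-marginal kappa as undefined", {
  m <- rm2(rep("SIRS", 5), rep("SIRS", 5))
  kx <- kappa_fixed(m)
  expect_true(is.na(kx))
  expect_true(attr(kx, "undefined"))
  # but the free-marginal kappa is still defined (perfect agreement)
  expect_equal(kappa_free(m), 1)
})

test_that("kappa statistics agree with brute-force oracles on enumerated matrices", {
  cats <- category_levels()
  # all 729 two-rater matrices with N = 3 items
  grid <- expand.grid(rep(list(1:3), 6))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    calls <- cbind(cats[g[1:3]], cats[g[4:6]])
    m <- rating_matrix(calls, categories = cats)
    expect_equal(overall_agreement(m), oracle_po(calls))
    expect_equal(kappa_free(m), oracle_randolph(calls, 3))
    expect_equal(as.numeric(kappa_fixed(m, method = "fleiss")),
                 oracle_fleiss(calls, cats))
    expect_equal(as.numeric(kappa_fixed(m, method = "cohen")),
                 oracle_cohen(calls, cats))
  }
})

test_that("three-rater Fleiss kappa matches the brute-force oracle", {
  cats <- category_levels()
  set.seed(42)
  for (r in 1:200) {
    calls <- matrix(sample(cats, 8 * 3, replace = TRUE), nrow = 8)
    m <- rating_matrix(calls, categories = cats)
    expect_equal(as.numeric(kappa_fixed(m, method = "fleiss")),
                 oracle_fleiss(calls, cats))
    expect_equal(overall_agreement(m), oracle_po(calls))
  }
})

test_that("relabeling categories leaves all agreement statistics unchanged", {
  set.seed(7)
  cats <- category_levels()
  calls <- matrix(sample(cats, 40 * 2, replace = TRUE, prob = c(0.5, 0.2, 0.3)),
                  nrow = 40)
  m <- rating_matrix(calls, categories = cats)
  perm <- c(SIRS = "sepsis", indeterminate = "SIRS", sepsis = "indeterminate")
  calls_p <- matrix(perm[calls], nrow = 40)
  mp <- rating_matrix(calls_p, categories = cats)
  expect_equal(overall_agreement(mp), overall_agreement(m))
  expect_equal(kappa_free(mp), kappa_free(m))
  expect_equal(as.numeric(kappa_fixed(mp)), as.numeric(kappa_fixed(m)))
})

test_that("pooled fixed-marginal kappa never exceeds the free-marginal kappa", {
  set.seed(123)
  for (r in 1:500) {
    k <- sample(2:4, 1)
    n <- sample(2:4, 1)
    N <- sample(3:12, 1)
    cats <- paste0("c", 1:k)
    calls <- matrix(sample(cats, N * n, replace = TRUE,
                           prob = runif(k)), nrow = N)
    m <- rating_matrix(calls, categories = cats)
    kx <- kappa_fixed(m, method = "fleiss")
    if (is.na(kx)) next
    expect_lte(as.numeric(kx), kappa_free(m) + 1e-12)
  }
})

test_that("bootstrap kappa interval behaves as a percentile CI", {
  # perfect agreement: degenerate interval at 1
  mp <- rm2(rep(category_levels(), 10), rep(category_levels(), 10))
  ci <- kappa_ci(mp, "free", reps = 200, seed = 1)
  expect_equal(c(ci$low, ci$high), c(1, 1))
  # interval contains the point estimate
  set.seed(5)
  a <- sample(category_levels(), 200, replace = TRUE)
  b <- ifelse(runif(200) < 0.7, a, sample(category_levels(), 200, replace = TRUE))
  m <- rm2(a, b)
  ci <- kappa_ci(m, "free", reps = 500, seed = 2)
  expect_lte(ci$low, ci$estimate)
  expect_gte(ci$high, ci$estimate)
  # deterministic under seed
  ci2 <- kappa_ci(m, "free", reps = 500, seed = 2)
  expect_identical(ci, ci2)
  ci_fixed <- kappa_ci(m, "fixed", reps = 300, seed = 3)
  expect_lte(ci_fixed$low, ci_fixed$estimate)
  expect_gte(ci_fixed$high, ci_fixed$estimate)
  expect_error(kappa_ci(m, "free", reps = 100), "at least 200")
})

test_that("free/fixed kappa ratio responds to marginal skew", {
  # uniform marginals: the two chance corrections coincide, ratio ~ 1
  prof_u <- kappa_ratio_profile(c(1, 1, 1) / 3, agreement = 0.7,
                                sample_sizes = c(50, 100), nsim = 40, seed = 4)
  expect_true(all(abs(prof_u$mean_ratio - 1) < 0.05))
  # skewed marginals: fixed-marginal chance agreement is larger, so
  # kappa_fixed < kappa_free and the ratio exceeds 1
  prof_s <- kappa_ratio_profile(c(0.8, 0.1, 0.1), agreement = 0.7,
                                sample_sizes = c(50, 100), nsim = 40, seed = 4)
  expect_true(all(prof_s$mean_ratio > 1.05))
  # direct formula check at fixed P_o = 0.7: skew lowers kappa_fixed
  p <- c(0.8, 0.1, 0.1)
  kf <- kappa_free_from_agreement(0.7, 3)
  kx <- (0.7 - sum(p^2)) / (1 - sum(p^2))
  expect_lt(kx, kf)
})

test_that("agreement_result bundles the statistics consistently", {
  set.seed(11)
  a <- sample(category_levels(), 100, replace = TRUE)
  b <- ifelse(runif(100) < 0.6, a, sample(category_levels(), 100, replace = TRUE))
  m <- rm2(a, b)
  res <- agreement_result(m, comparison_id = "demo")
  expect_equal(res$kappa_free, (res$p_o - 1 / 3) / (1 - 1 / 3))
  expect_equal(res$N, 100)
  expect_lte(res$kappa_fixed, res$kappa_free + 1e-9)
})
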