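test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(prevalence = c(SIRS = 0.5, indeterminate = 0.4,
                                            sepsis = 0.2)),
               "prevalence")
  bad_conf <- default_rater_confusion()
  bad_conf$attending[1, 1] <- 0.9  # row no longer sums to 1
  expect_error(cohort_config(rater_confusion = bad_conf), "attending")
  expect_error(cohort_config(missingness = c(PCT = 1)), "missingness")
  expect_error(cohort_config(n_patients = 0), "n_patients")
})

test_that("generation is deterministic under the seed, down to bytes on disk", {
  cfg <- cohort_config(n_patients = 120, seed = 99)
  d1 <- generate_cohort(cfg, include_latent = TRUE)
  d2 <- generate_cohort(cfg, include_latent = TRUE)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(d1, f1); write_cohort(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # round-trip preserves the table contents
  rt <- read_cohort(f1)
  expect_equal(nrow(rt), 120)
  expect_identical(rt$antibiotics, d1$antibiotics)
  # a different seed gives a different table
  d3 <- generate_cohort(cohort_config(n_patients = 120, seed = 100))
  expect_false(identical(d1$call_attending, d3$call_attending))
  unlink(c(f1, f2))
})

test_that("every emitted record meets the two-criterion inclusion filter", {
  d <- generate_cohort(cohort_config(n_patients = 400, seed = 12))
  expect_equal(nrow(d), 400)
  expect_true(all(count_sirs_criteria(d) >= 2))
  expect_true(all(d$N.SIRS >= 2))
  expect_true(all(d$N.SIRS == count_sirs_criteria(d)))
  # physiologic sanity
  expect_true(all(d$Temp.Max >= 30 & d$Temp.Max <= 45))
  expect_true(all(d$WBC.Max[!is.na(d$WBC.Max)] >= 0))
  expect_true(all(d$HeartRate.Max >= 0))
  expect_true(all(d$ICU.LoS >= 0))
})

test_that("systemic-inflammation criteria count follows the strict thresholds", {
  rec <- function(...) data.frame(...)
  expect_equal(count_sirs_criteria(rec(Temp.Max = 39, HeartRate.Max = 100,
                                       RR.Max = 22, WBC.Max = 13)), 4L)
  expect_equal(count_sirs_criteria(rec(Temp.Max = 37, HeartRate.Max = 80,
                                       RR.Max = 16, WBC.Max = 8)), 0L)
  # boundary literals are strict: WBC exactly 4 (10^3/mm^3) does not count
  expect_equal(count_sirs_criteria(rec(Temp.Max = 37, HeartRate.Max = 80,
                                       RR.Max = 16, WBC.Min = 4, WBC.Max = 8)), 0L)
  # hypothermia and low PaCO2 routes
  expect_equal(count_sirs_criteria(rec(Temp.Min = 35.5, PaCO2 = 30)), 2L)
  # immature neutrophils route; missing fields contribute nothing
  expect_equal(count_sirs_criteria(rec(Immature.Neutrophils = 12)), 1L)
  expect_equal(count_sirs_criteria(rec(Temp.Max = NA, HeartRate.Max = 95)), 1L)
})

test_that("class-conditional covariate means are recovered at large n", {
  cfg <- cohort_config(n_patients = 6000, seed = 31)
  d <- generate_cohort(cfg, include_latent = TRUE)
  # covariates independent of the inclusion filter (which conditions on
  # vitals): compare per-class sample means to the configured locations
  params <- cfg$covariate_params
  # analytic mean of the truncated normal the generator draws from
  tn_mean <- function(m, s, lo, hi) {
    a <- (lo - m) / s; b <- (hi - m) / s
    m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (cov in c("Age", "MAP.Min", "SeptiScore", "Glucose.Min")) {
    for (ci in 1:3) {
      cls <- category_levels()[ci]
      x <- d[[cov]][d$latent_class == cls]
      x <- x[!is.na(x)]
      p <- params[[cov]]
      target <- tn_mean(p$mean[ci], p$sd, p$lower, p$upper)
      se <- p$sd / sqrt(length(x))
      expect_lt(abs(mean(x) - target), 3.5 * se + 0.3,
                label = paste(cov, cls))
    }
  }
  # PCT is log-normal with class-ordered location
  med <- tapply(d$PCT, d$latent_class, median, na.rm = TRUE)
  expect_true(med[["SIRS"]] < med[["indeterminate"]])
  expect_true(med[["indeterminate"]] < med[["sepsis"]])
})

test_that("empirical call distributions recover the configured confusion rows", {
  cfg <- cohort_config(n_patients = 6000, seed = 32)
  d <- generate_cohort(cfg, include_latent = TRUE)
  conf <- cfg$rater_confusion$attending
  for (ci in 1:3) {
    cls <- category_levels()[ci]
    calls <- d$call_attending[d$latent_class == cls]
    n <- length(calls)
    emp <- table(factor(calls, levels = call_levels())) / n
    for (j in seq_along(call_levels())) {
      p <- conf[ci, j]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(emp[[j]] - p), 3.5 * se + 0.005)
    }
  }
})

test_that("latent prevalence and hospital cohorts follow the configuration", {
  d <- generate_cohort(cohort_config(n_patients = 6000, seed = 33),
                       include_latent = TRUE)
  prev <- table(d$latent_class) / nrow(d)
  expect_equal(unname(prev[["SIRS"]]), 106 / 249, tolerance = 0.03)
  expect_equal(unname(prev[["sepsis"]]), 69 / 249, tolerance = 0.03)
  expect_setequal(unique(d$cohort_label), c("V", "Vs"))
  expect_true(all(d$hospital[d$cohort_label == "V"] %in% c("IMC", "LDSH")))
  # V enrols roughly 129/249 of patients
  expect_equal(mean(d$cohort_label == "V"), 129 / 249, tolerance = 0.03)
})

test_that("antibiotic assignment is forced for sepsis and calibrated for SIRS", {
  cfg <- cohort_config(n_patients = 9000, seed = 34)
  d <- generate_cohort(cfg, include_latent = TRUE)
  expect_true(all(d$antibiotics[d$latent_class == "sepsis"]))
  frac_sirs <- mean(d$antibiotics[d$latent_class == "SIRS"])
  expect_lt(abs(frac_sirs - 0.57), 0.05)
  frac_ind <- mean(d$antibiotics[d$latent_class == "indeterminate"])
  expect_gt(frac_ind, 0.8)
  # the assignment separates treated from untreated SIRS only weakly
  s <- d[d$latent_class == "SIRS", ]
  y <- logistic_score(cfg$antibiotic_model, s)$y
  auc <- roc_auc(y, s$antibiotics, ci = FALSE)$auc
  expect_gt(auc, 0.6)
  expect_lt(auc, 0.8)
})

test_that("degenerate assignment models behave as stated", {
  d <- generate_cohort(cohort_config(n_patients = 60, seed = 8),
                       include_latent = TRUE)
  huge <- logistic_model_spec("always", 50, c(Age = 0))
  expect_true(all(assign_antibiotics(d, huge,
                                     class_offset = c(SIRS = 0, indeterminate = 0,
                                                      sepsis = Inf))))
  # y = 0 gives a fair coin
  coin <- logistic_model_spec("coin", 0, c(Age = 0))
  set.seed(1)
  draws <- replicate(200, mean(assign_antibiotics(
    d[d$latent_class != "sepsis", ], coin,
    class_offset = c(SIRS = 0, indeterminate = 0, sepsis = Inf))))
  expect_lt(abs(mean(draws) - 0.5), 0.05)
})

test_that("missingness is explicit and respects configured fractions", {
  cfg <- cohort_config(n_patients = 5000, seed = 35)
  d <- generate_cohort(cfg)
  expect_gt(mean(is.na(d$pH)), 0.5)
  expect_equal(mean(is.na(d$PCT)), cfg$missingness[["PCT"]], tolerance = 0.03)
  expect_false(anyNA(d$SeptiScore))
  # multi-site infections occur but rarely, and never combine with "none"
  multi <- grepl(";", d$infection_sites)
  expect_lt(mean(multi), 0.02)
  expect_false(any(grepl("none", d$infection_sites[multi])))
})

test_that("dependence knobs shift agreement in the expected direction", {
  # panel adopting the local reference raises local-vs-external agreement
  base_cfg <- cohort_config(n_patients = 1500, seed = 55)
  dep_cfg <- cohort_config(n_patients = 1500, seed = 55,
                           rpd_follows_discharge = 0.6)
  f_base <- run_all(derive_evaluations(generate_cohort(base_cfg)),
                    comparison_specs("F"))$kappa_free
  f_dep <- run_all(derive_evaluations(generate_cohort(dep_cfg)),
                   comparison_specs("F"))$kappa_free
  expect_gt(f_dep, f_base + 0.05)
  # a shared per-patient difficulty effect inflates "possible" calls
  hard_cfg <- cohort_config(n_patients = 1500, seed = 56,
                            shared_difficulty = 3)
  d_hard <- generate_cohort(hard_cfg)
  d_base <- generate_cohort(cohort_config(n_patients = 1500, seed = 56))
  expect_gt(mean(d_hard$call_attending == "possible"),
            mean(d_base$call_attending == "possible") + 0.03)
  expect_error(cohort_config(rpd_follows_discharge = 1.5),
               "rpd_follows_discharge")
})
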