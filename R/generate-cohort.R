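draw_covariate <- function(spec, class_idx) {
  n <- length(class_idx)
  if (spec$dist == "truncnorm") {
    x <- rtruncnorm(n, spec$mean[class_idx], spec$sd, spec$lower, spec$upper)
    if (isTRUE(spec$integer)) x <- pmax(ceiling(spec$lower), round(x))
    x
  } else if (spec$dist == "lognormal") {
    pmax(spec$floor, rlnorm(n, spec$meanlog[class_idx], spec$sdlog))
  } else if (spec$dist == "bernoulli") {
    b <- runif(n) < spec$prob[class_idx]
    if (is.null(spec$labels)) as.integer(b) else spec$labels[b + 1L]
  } else {
    stop("unknown covariate distribution '", spec$dist, "'", call. = FALSE)
  }
}

draw_calls <- function(confusion, class_idx, difficulty_w = NULL) {
  n <- length(class_idx)
  out <- character(n)
  for (cls in 1:3) {
    idx <- which(class_idx == cls)
    if (!length(idx)) next
    if (is.null(difficulty_w)) {
      out[idx] <- sample(call_levels(), length(idx), replace = TRUE,
                         prob = confusion[cls, ])
    } else {
      # per-patient mixture toward the "possible" call
      for (i in idx) {
        w <- difficulty_w[i]
        p <- (1 - w) * confusion[cls, ]
        p["possible"] <- p["possible"] + w
        out[i] <- sample(call_levels(), 1, prob = p)
      }
    }
  }
  out
}

#' Assign antibiotic treatment
#'
#' Bernoulli treat/no-treat draw with probability
#' \code{plogis(y + offset[class])}, where y is the linear predictor of the
#' assignment model evaluated on the record and the offset shifts whole
#' latent classes (an infinite offset forces treatment, the rule applied to
#' septic patients). Missing model covariates are imputed by the latent
#' class mean of the configured generator distribution, since the decision
#' is made at generation time where the truth is known.
#'
#' @param data data frame of records carrying the model covariates and
#'   \code{latent_class}.
#' @param model a [logistic_model_spec()].
#' @param class_offset named logit offsets per latent class.
#' @param latent latent class factor (defaults to
#'   \code{data$latent_class}).
#' @return logical vector of treatment indicators.
#' @export
assign_antibiotics <- function(data, model = default_antibiotic_model(),
                               class_offset = c(SIRS = 0, indeterminate = 2.25,
                                                sepsis = Inf),
                               latent = data$latent_class) {
  latent <- parse_category(latent)
  data <- as.data.frame(data)
  # impute missing model covariates by the latent-class mean before scoring
  for (cv in names(model$coefficients)) {
    if (!cv %in% names(data)) next
    x <- as.numeric(data[[cv]])
    if (anyNA(x)) {
      mu <- tapply(x, latent, mean, na.rm = TRUE)
      x[is.na(x)] <- mu[as.character(latent)[is.na(x)]]
      data[[cv]] <- x
    }
  }
  sc <- logistic_score(model, data)
  y <- sc$y + unname(class_offset[as.character(latent)])
  p <- plogis(y)
  p[is.na(p)] <- 0.5
  runif(length(p)) < p
}

#' Generate a synthetic ICU line-data cohort
#'
#' Draws a patient-level table with the statistical structure the agreement
#' analysis assumes: a latent 3-class diagnosis (SIRS / indeterminate /
#' sepsis) drawn from the configured prevalence; eight evaluator calls
#' (attending, initial site investigator, two discharge site investigators,
#' adjudicator, three external panelists) drawn per role from
#' class-conditional confusion matrices; class-conditional clinical
#' covariates (truncated normals within physiologic bounds; log-normal
#' procalcitonin floored at 0.05 ng/mL); infection sites; an antibiotic
#' treatment flag from a weakly separable logistic assignment model; and
#' per-covariate missingness (explicit \code{NA}, never imputed).
#'
#' Every emitted record satisfies the study inclusion criterion of at least
#' two systemic-inflammation criteria, evaluated on the record as emitted
#' (i.e. after missingness masking): rows failing the criterion are
#' redrawn. The adjudicator call is reported only for patients whose two
#' discharge investigators disagree on the mapped category. Output is
#' bit-identical for identical config and seed.
#'
#' @param config a [cohort_config()].
#' @param include_latent keep the generator-only \code{latent_class}
#'   column? Default \code{FALSE}, so the table matches what an analyst
#'   would see.
#' @return tibble with one row per patient.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 50, seed = 7),
#'                           include_latent = TRUE)
#' table(cohort$latent_class)
#' @export
generate_cohort <- function(config = cohort_config(), include_latent = FALSE) {
  validate_cohort_config(config)
  n <- config$n_patients
  cats <- category_levels()
  with_seed(config$seed, {
    latent <- sample(1:3, n, replace = TRUE,
                     prob = config$prevalence[cats])

    hosp_w <- config$hospital_labels$weights
    hospital <- sample(names(hosp_w), n, replace = TRUE,
                       prob = hosp_w / sum(hosp_w))
    cohort_label <- ifelse(hospital %in% config$hospital_labels$cohort_v,
                           "V", "Vs")

    # covariates + missingness mask, redrawn until the emitted record
    # meets >= 2 systemic-inflammation criteria
    cov_names <- names(config$covariate_params)
    cov <- as.data.frame(matrix(NA_real_, n, 0))
    todo <- seq_len(n)
    tries <- 0
    while (length(todo)) {
      tries <- tries + 1
      if (tries > 1000) stop("inclusion criterion unsatisfiable under this configuration", call. = FALSE)
      draw <- lapply(config$covariate_params, draw_covariate, latent[todo])
      draw <- as.data.frame(draw, optional = TRUE)
      names(draw) <- cov_names
      for (nm in names(config$missingness)) {
        if (!nm %in% names(draw)) next
        hit <- runif(length(todo)) < config$missingness[[nm]]
        draw[[nm]][hit] <- NA
      }
      ok <- count_sirs_criteria(draw) >= 2
      if (tries == 1) cov <- draw[rep(1L, n), , drop = FALSE]
      cov[todo[ok], ] <- draw[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    rownames(cov) <- NULL
    n_sirs <- count_sirs_criteria(cov)

    difficulty_w <- if (config$shared_difficulty > 0) {
      plogis(rnorm(n, 0, config$shared_difficulty) - 2)
    } else {
      NULL
    }
    calls <- lapply(config$rater_confusion[evaluator_roles()], draw_calls,
                    latent, difficulty_w)

    # adjudicator only participates when the discharge investigators
    # disagree on the mapped category
    d1 <- map_call(calls$investigator_discharge_1)
    d2 <- map_call(calls$investigator_discharge_2)
    adjudicator_full <- calls$adjudicator
    calls$adjudicator[d1 == d2] <- NA_character_

    # optional dependence of the panel on the local reference: a panelist
    # who read the investigators' consensus may simply adopt it
    if (config$rpd_follows_discharge > 0) {
      cons <- as.character(consensus_discharge(
        calls$investigator_discharge_1, calls$investigator_discharge_2,
        adjudicator_full))
      cons_call <- c(SIRS = "none", indeterminate = "possible",
                     sepsis = "probable")[cons]
      for (role in c("rpd_1", "rpd_2", "rpd_3")) {
        adopt <- runif(n) < config$rpd_follows_discharge
        calls[[role]][adopt] <- cons_call[adopt]
      }
    }

    # infection sites; a patient with an identified site may carry a second
    sites <- character(n)
    site_m <- config$site_distribution
    for (cls in 1:3) {
      idx <- which(latent == cls)
      if (!length(idx)) next
      sites[idx] <- sample(site_levels(), length(idx), replace = TRUE,
                           prob = site_m[cls, ])
    }
    extra <- runif(n) < config$multi_site_prob & sites != "none"
    for (i in which(extra)) {
      pool <- setdiff(site_levels(), c("none", sites[i]))
      sites[i] <- paste(sort(c(sites[i], sample(pool, 1))), collapse = ";")
    }

    tab <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      cohort_label = cohort_label,
      hospital = hospital,
      latent_class = factor(cats[latent], levels = cats),
      call_attending = calls$attending,
      call_investigator_initial = calls$investigator_initial,
      call_investigator_discharge_1 = calls$investigator_discharge_1,
      call_investigator_discharge_2 = calls$investigator_discharge_2,
      call_adjudicator = calls$adjudicator,
      call_rpd_1 = calls$rpd_1,
      call_rpd_2 = calls$rpd_2,
      call_rpd_3 = calls$rpd_3,
      infection_sites = sites,
      N.SIRS = n_sirs
    )
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(cov))
    tab$antibiotics <- assign_antibiotics(tab, config$antibiotic_model,
                                          config$antibiotic_class_offset)
    tab$antibiotics[latent == 3] <- TRUE
    if (!include_latent) tab$latent_class <- NULL
    tab
  })
}

#' Read / write a line-data table as CSV
#'
#' One header row, missing values as empty cells. \code{read_cohort}
#' restores the logical antibiotics flag.
#'
#' @param data cohort tibble.
#' @param path file path.
#' @return \code{read_cohort} returns a tibble; \code{write_cohort} its
#'   path, invisibly.
#' @export
write_cohort <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  if ("antibiotics" %in% names(df)) df$antibiotics <- as.logical(df$antibiotics)
  tibble::as_tibble(df)
}
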