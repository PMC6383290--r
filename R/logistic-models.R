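# Transform registry: transforms are named symbolically so model specs
# round-trip through JSON and reproduce identical scores.
transform_registry <- list(
  identity = function(x) x,
  # procalcitonin enters discriminant models as log2 PCT; values are floored
  # at 0.05 ng/mL (a detection-limit convention) so the log is defined.
  log2_detection_floor = function(x) log2(pmax(x, 0.05))
)

#' Define a logistic discriminant model
#'
#' A named linear predictor \eqn{y = \beta_0 + \sum_j \beta_j x_j} over
#' patient-record covariates, with optional symbolic covariate transforms
#' (currently \code{"identity"} and \code{"log2_detection_floor"}, the
#' log2-with-0.05-floor used for procalcitonin). Scores are converted to
#' probabilities by the logistic function.
#'
#' @param name model name.
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector of covariate weights; names must
#'   resolve against record columns.
#' @param transforms optional named character vector mapping covariate name
#'   to a transform in the registry.
#' @return object of class \code{logistic_model_spec}.
#' @export
logistic_model_spec <- function(name, intercept, coefficients,
                                transforms = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1, is.finite(intercept),
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))), all(is.finite(coefficients)))
  if (!is.null(transforms)) {
    bad <- setdiff(unname(transforms), names(transform_registry))
    if (length(bad)) stop("unknown transform(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(list(name = name, intercept = unname(intercept),
                 coefficients = coefficients, transforms = transforms),
            class = "logistic_model_spec")
}

#' @export
print.logistic_model_spec <- function(x, ...) {
  terms <- sprintf("%+.4f * %s", x$coefficients, names(x$coefficients))
  cat(sprintf("logistic model '%s':\n  y = %.4f %s\n", x$name, x$intercept,
              paste(terms, collapse = " ")))
  invisible(x)
}

#' Built-in discriminant model presets
#'
#' Four published scoring equations over ICU line-data covariates:
#' \describe{
#'   \item{sepsis_vs_indeterminate}{separates septic from indeterminate
#'     patients using SeptiScore, WBC extremes and maximum MAP.}
#'   \item{sirs_vs_indeterminate}{separates SIRS from indeterminate patients
#'     using log2 procalcitonin and SeptiScore.}
#'   \item{antibiotics_sirs_5var}{separates antibiotic-treated from untreated
#'     SIRS patients (MAP.Min, HR.Max, Temp.Max, Hospital.LoS, N.SIRS).}
#'   \item{antibiotics_sirs_4var}{the 4-variable variant without hospital
#'     length of stay.}
#' }
#'
#' @param name preset name; omit to list available names.
#' @return a [logistic_model_spec()] (or character vector of names).
#' @examples
#' preset_model("sepsis_vs_indeterminate")
#' @export
preset_model <- function(name = NULL) {
  presets <- list(
    sepsis_vs_indeterminate = logistic_model_spec(
      "sepsis_vs_indeterminate", 0.4249,
      c(SeptiScore = 0.3672, WBC.Max = 0.1232, WBC.Min = -0.0245,
        MAP.Max = -0.0269)),
    sirs_vs_indeterminate = logistic_model_spec(
      "sirs_vs_indeterminate", 3.1742,
      c(PCT = -0.2548, SeptiScore = -0.3913),
      transforms = c(PCT = "log2_detection_floor")),
    antibiotics_sirs_5var = logistic_model_spec(
      "antibiotics_sirs_5var", -17.8210,
      c(MAP.Min = -0.0200, HR.Max = 0.0128, Temp.Max = 0.4540,
        Hospital.LoS = 0.0906, N.SIRS = 0.2472)),
    antibiotics_sirs_4var = logistic_model_spec(
      "antibiotics_sirs_4var", -16.5106,
      c(MAP.Min = -0.0239, HR.Max = 0.0125, Temp.Max = 0.4372,
        N.SIRS = 0.2386))
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; see preset_model()", call. = FALSE)
  }
  presets[[name]]
}

#' Score records with a logistic discriminant model
#'
#' Evaluates the linear predictor y (and probability \code{plogis(y)}) for
#' each record. Model covariates must exist as columns; records with a
#' missing covariate value are flagged and scored \code{NA} — there is no
#' silent imputation.
#'
#' @param model a [logistic_model_spec()].
#' @param data data frame of patient records. Heart-rate covariates are
#'   accepted under either \code{HR.Max/HR.Min} or
#'   \code{HeartRate.Max/HeartRate.Min}.
#' @return tibble with columns \code{y}, \code{probability},
#'   \code{missing_covariates} (comma-separated names, \code{NA} if none).
#' @export
logistic_score <- function(model, data) {
  stopifnot(inherits(model, "logistic_model_spec"))
  data <- as.data.frame(data)
  alias <- c(HR.Max = "HeartRate.Max", HR.Min = "HeartRate.Min")
  covs <- names(model$coefficients)
  vals <- matrix(NA_real_, nrow(data), length(covs),
                 dimnames = list(NULL, covs))
  for (cv in covs) {
    col <- if (cv %in% names(data)) cv
           else if (cv %in% names(alias) && alias[[cv]] %in% names(data)) alias[[cv]]
           else stop("model covariate '", cv, "' not found in data", call. = FALSE)
    x <- as.numeric(data[[col]])
    tr <- if (!is.null(model$transforms) && cv %in% names(model$transforms)) {
      transform_registry[[model$transforms[[cv]]]]
    } else {
      transform_registry$identity
    }
    vals[, cv] <- tr(x)
  }
  miss <- apply(vals, 1, function(r) paste(covs[is.na(r)], collapse = ","))
  miss[!nzchar(miss)] <- NA_character_
  y <- model$intercept + as.vector(vals %*% model$coefficients)
  tibble::tibble(y = y, probability = plogis(y), missing_covariates = miss)
}

#' Serialize / deserialize a model spec as JSON
#'
#' Round-trips exactly: a reloaded spec reproduces identical scores bitwise
#' (coefficients are written at full precision, transforms symbolically).
#'
#' @param model a [logistic_model_spec()].
#' @param path file path.
#' @return \code{read_model_spec} returns the model; \code{write_model_spec}
#'   its path, invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "logistic_model_spec"))
  jsonlite::write_json(
    list(name = model$name, intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         transforms = as.list(model$transforms)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path)
  logistic_model_spec(
    x$name, as.numeric(x$intercept),
    setNames(vapply(x$coefficients, as.numeric, numeric(1)),
             names(x$coefficients)),
    transforms = if (length(x$transforms)) {
      setNames(vapply(x$transforms, as.character, character(1)),
               names(x$transforms))
    } else NULL)
}

#' Fit a logistic discriminant model by maximum likelihood
#'
#' Complete-case binomial GLM over the named covariates. Quasi-complete or
#' complete separation is detected (non-convergence, exploding
#' coefficients, or fitted probabilities pinned at 0/1); in that case the
#' coefficient estimates are withheld and the fit flagged, since the MLE
#' does not exist.
#'
#' @param data data frame of records.
#' @param outcome name of a binary outcome column (logical, 0/1, or
#'   two-level factor).
#' @param covariates character vector of covariate column names.
#' @param min_events minimum events per class before a warning (default 10).
#' @return list of class \code{logistic_fit}: \code{spec} (a
#'   [logistic_model_spec()], \code{NULL} if separated), \code{se},
#'   \code{converged}, \code{separation}, \code{n}, \code{n_events}.
#' @export
fit_logistic <- function(data, outcome, covariates, min_events = 10) {
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y)) {
    lv <- sort(unique(as.character(y[!is.na(y)])))
    if (length(lv) != 2) stop("outcome must be binary", call. = FALSE)
    y <- as.character(y) == lv[2]
  }
  y <- as.numeric(y)
  X <- data[, covariates, drop = FALSE]
  keep <- complete.cases(X) & !is.na(y)
  X <- as.data.frame(lapply(X[keep, , drop = FALSE], as.numeric))
  y <- y[keep]
  if (min(sum(y), sum(1 - y)) < min_events) {
    warning("fewer than ", min_events, " events in one class", call. = FALSE)
  }
  df <- cbind(.outcome = y, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.outcome ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- coef(fit)
  separation <- sep_warn && (!fit$converged || max(abs(cf[-1])) > 15)
  se <- sqrt(diag(vcov(fit)))
  spec <- if (separation) NULL else {
    logistic_model_spec(paste0("fit_", outcome), cf[1],
                        setNames(cf[-1], covariates))
  }
  structure(list(spec = spec, se = setNames(se, c("(Intercept)", covariates)),
                 converged = fit$converged, separation = separation,
                 n = length(y), n_events = sum(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$separation) {
    cat(sprintf("logistic fit (n = %d): separation detected; coefficients withheld\n", x$n))
  } else {
    cat(sprintf("logistic fit (n = %d, events = %d, converged = %s)\n",
                x$n, x$n_events, x$converged))
    print(x$spec)
  }
  invisible(x)
}
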