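# ---- default configuration pieces -------------------------------------

tn_spec <- function(mean, sd, lower = -Inf, upper = Inf, integer = FALSE) {
  list(dist = "truncnorm", mean = mean, sd = sd, lower = lower, upper = upper,
       integer = integer)
}
ln_spec <- function(meanlog, sdlog, floor = 0.05) {
  list(dist = "lognormal", meanlog = meanlog, sdlog = sdlog, floor = floor)
}
bn_spec <- function(prob, labels = NULL) {
  list(dist = "bernoulli", prob = prob, labels = labels)
}

#' Rater confusion matrices
#'
#' A confusion matrix maps the latent 3-class diagnosis (rows: SIRS,
#' indeterminate, sepsis) to probabilities over the four call levels
#' (columns: none, possible, probable, definite); rows are stochastic.
#' \code{confusion_from_accuracy(a)} builds a matrix in which each class
#' yields its modal call(s) with total probability \code{a} (split between
#' probable and definite for the sepsis class) and spreads the remainder
#' over neighbouring calls. \code{errorfree_rater_confusion()} is the
#' \code{a = 1} limit; \code{uniform_rater_confusion()} is uniform over the
#' four calls (note that after call-to-category mapping this is *not*
#' chance level on the 3-category scale, since two calls collapse to
#' sepsis); \code{chance_rater_confusion()} is uniform over the three
#' mapped categories, the configuration under which kappa is zero in
#' expectation.
#'
#' @param accuracy probability of the class-modal call, in (0, 1\].
#' @return a 3 x 4 row-stochastic matrix.
#' @export
confusion_from_accuracy <- function(accuracy) {
  a <- accuracy
  stopifnot(a > 0, a <= 1)
  m <- rbind(
    SIRS          = c(a, (1 - a) * 0.60, (1 - a) * 0.30, (1 - a) * 0.10),
    indeterminate = c((1 - a) * 0.35, a, (1 - a) * 0.50, (1 - a) * 0.15),
    sepsis        = c((1 - a) * 0.30, (1 - a) * 0.70, a * 0.60, a * 0.40)
  )
  colnames(m) <- call_levels()
  m
}

#' @rdname confusion_from_accuracy
#' @export
errorfree_rater_confusion <- function() {
  roles <- evaluator_roles()
  setNames(lapply(roles, function(r) confusion_from_accuracy(1)), roles)
}

#' @rdname confusion_from_accuracy
#' @export
uniform_rater_confusion <- function() {
  m <- matrix(0.25, 3, 4, dimnames = list(category_levels(), call_levels()))
  roles <- evaluator_roles()
  setNames(lapply(roles, function(r) m), roles)
}

#' @rdname confusion_from_accuracy
#' @export
chance_rater_confusion <- function() {
  m <- matrix(rep(c(1/3, 1/3, 1/6, 1/6), each = 3), 3, 4,
              dimnames = list(category_levels(), call_levels()))
  roles <- evaluator_roles()
  setNames(lapply(roles, function(r) m), roles)
}

#' Evaluator roles of the adjudication design
#'
#' One attending physician at admission, one site investigator at
#' admission, two site investigators at discharge plus an adjudicator for
#' their disagreements, and three external expert (RPD) panelists.
#'
#' @return character vector of role names.
#' @export
evaluator_roles <- function() {
  c("attending", "investigator_initial", "investigator_discharge_1",
    "investigator_discharge_2", "adjudicator", "rpd_1", "rpd_2", "rpd_3")
}

# Default per-role confusion: the attending's admission call is noisiest
# (least information, under time pressure); the investigator's initial call
# is better; discharge-stage reviewers and panelists see the full chart.
default_rater_confusion <- function() {
  acc <- c(attending = 0.79, investigator_initial = 0.82,
           investigator_discharge_1 = 0.83, investigator_discharge_2 = 0.83,
           adjudicator = 0.83, rpd_1 = 0.82, rpd_2 = 0.82, rpd_3 = 0.82)
  lapply(acc, confusion_from_accuracy)
}

# Class-conditional covariate distributions (class order SIRS,
# indeterminate, sepsis). Locations follow the cohort-description
# directionality: indeterminate/septic patients are older, sicker (higher
# APACHE/SOFA), stay longer, and have higher PCT and SeptiScore; treated
# groups sit at lower minimum MAP and higher maximum heart rate and
# temperature. Vitals are truncated to physiologic bands.
default_covariate_params <- function() {
  list(
    Age           = tn_spec(c(52, 63, 57), 15, 18, 89, integer = TRUE),
    HeartRate.Max = tn_spec(c(107, 108, 112), 14, 40, 220),
    HeartRate.Min = tn_spec(c(76, 78, 80), 12, 20, 180),
    MAP.Max       = tn_spec(c(96, 92, 90), 12, 50, 160),
    MAP.Min       = tn_spec(c(64, 60, 55), 14, 25, 120),
    Temp.Max      = tn_spec(c(38.3, 38.0, 38.4), 0.8, 30, 45),
    Temp.Min      = tn_spec(c(36.3, 36.2, 36.0), 0.6, 30, 45),
    RR.Max        = tn_spec(c(25, 26, 27), 5, 8, 60),
    WBC.Max       = tn_spec(c(13.5, 14, 16), 4.5, 0.5, 60),
    WBC.Min       = tn_spec(c(8, 8.5, 9), 3, 0.2, 40),
    Glucose.Max   = tn_spec(c(150, 160, 165), 50, 50, 600),
    Glucose.Min   = tn_spec(c(95, 100, 100), 22, 30, 300),
    APACHE        = tn_spec(c(55, 80, 72), 28, 0, 200, integer = TRUE),
    SOFA          = tn_spec(c(4.5, 6, 6.5), 2.5, 0, 24, integer = TRUE),
    Lactate       = tn_spec(c(1.8, 2.2, 2.6), 1.0, 0.2, 15),
    pH            = tn_spec(c(7.38, 7.36, 7.34), 0.07, 6.8, 7.8),
    PCT           = ln_spec(log(c(0.4, 1.0, 5.0)), 1.4),
    SeptiScore    = tn_spec(c(3.6, 5.0, 6.4), 1.7, 0, 10),
    ICU.LoS       = tn_spec(c(2, 3, 4), 1.8, 0.5, 60, integer = TRUE),
    Hospital.LoS  = tn_spec(c(4, 7, 9), 4, 1, 90, integer = TRUE),
    Mortality     = bn_spec(c(0.06, 0.12, 0.13)),
    Sex           = bn_spec(c(0.48, 0.49, 0.44), labels = c("male", "female")),
    Race          = bn_spec(c(0.64, 0.72, 0.59), labels = c("non-white", "white"))
  )
}

#' Infection site categories
#' @return character vector of site labels.
#' @export
site_levels <- function() {
  c("respiratory_nonlung", "lung", "abdominal", "urinary", "other", "none")
}

# Per-class probabilities over infection sites; "none" means no site was
# identified. SIRS patients essentially never have an identified site;
# indeterminates skew respiratory; septic patients spread across sites.
default_site_distribution <- function() {
  m <- rbind(
    SIRS          = c(0.00, 0.03, 0.00, 0.00, 0.00, 0.97),
    indeterminate = c(0.05, 0.32, 0.03, 0.04, 0.05, 0.51),
    sepsis        = c(0.04, 0.22, 0.15, 0.12, 0.30, 0.17)
  )
  colnames(m) <- site_levels()
  m
}

#' Default antibiotic-assignment model
#'
#' The treat/no-treat decision for non-septic patients is modelled as a
#' Bernoulli draw on a logistic score over the same clinical drivers seen
#' in antibiotic-use screens (lower minimum MAP, tachycardia, fever, more
#' systemic-inflammation criteria). Coefficients are deliberately weak: the
#' separability between treated and untreated SIRS patients is calibrated
#' to an AUC of about 0.7 with a treated fraction near 0.57, the regime the
#' analysis machinery is designed to probe. Septic patients are always
#' treated; indeterminate patients receive a positive class offset (see
#' [cohort_config()]).
#'
#' @return a [logistic_model_spec()].
#' @export
default_antibiotic_model <- function() {
  logistic_model_spec(
    "antibiotic_assignment", -23.10,
    c(MAP.Min = -0.0323, HR.Max = 0.0169, Temp.Max = 0.5902,
      N.SIRS = 0.3221))
}

# Hospital enrolment weights; the first two sites form the validation
# cohort "V", the remainder the supplemental cohort "Vs".
default_hospitals <- function() {
  list(weights = c(IMC = 125, LDSH = 4, JHH = 39, RUMC = 37, LUMC = 11,
                   NH = 26, GMH = 7),
       cohort_v = c("IMC", "LDSH"))
}

# Available-case fractions modelled on a real ICU line-data table: blood
# gas and lactate panels are often absent, severity scores occasionally.
default_missingness <- function() {
  c(pH = 0.62, Lactate = 0.57, PCT = 0.35, SOFA = 0.30, MAP.Max = 0.22,
    Glucose.Max = 0.12, Glucose.Min = 0.12, Temp.Min = 0.03,
    MAP.Min = 0.02, APACHE = 0.01, WBC.Min = 0.01)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates everything the generator needs: cohort size, the
#' latent 3-class prevalence, per-role rater confusion matrices,
#' class-conditional covariate distributions, the infection-site model, the
#' antibiotic-assignment model, per-covariate missingness, hospital
#' enrolment weights, and the seed. Defaults emulate a 249-patient,
#' seven-hospital ICU cohort: prevalence 106/249 SIRS, 74/249
#' indeterminate, 69/249 sepsis; rater accuracies tuned so pairwise
#' free-marginal kappas fall in the 0.5-0.8 band.
#'
#' @param n_patients number of patients.
#' @param prevalence named 3-vector over SIRS/indeterminate/sepsis, sums
#'   to 1.
#' @param rater_confusion named list of 3 x 4 row-stochastic matrices, one
#'   per role in [evaluator_roles()].
#' @param covariate_params class-conditional distribution specs (see
#'   source of \code{default_covariate_params}).
#' @param site_distribution 3 x 6 row-stochastic matrix over
#'   [site_levels()].
#' @param antibiotic_model a [logistic_model_spec()] for the treat
#'   decision.
#' @param antibiotic_class_offset additive logit offsets per latent class;
#'   \code{Inf} forces treatment (default for sepsis).
#' @param missingness named vector of per-covariate missing fractions in
#'   \[0, 1).
#' @param hospital_labels list with \code{weights} (named sampling weights)
#'   and \code{cohort_v} (hospitals forming cohort V).
#' @param shared_difficulty standard deviation of an optional per-patient
#'   "difficulty" random effect that pushes all raters toward the
#'   "possible" call; 0 (default) disables it and raters are conditionally
#'   independent given the latent class.
#' @param rpd_follows_discharge probability that a panelist, who in the
#'   study design saw the site investigators' consensus discharge
#'   evaluation, simply adopts it. 0 (default) keeps the panel independent;
#'   positive values reproduce the elevated local-vs-external agreement
#'   that this information sharing induces.
#' @param multi_site_prob probability that a patient with an identified
#'   site carries a second site.
#' @param seed integer seed; the same config and seed give a bit-identical
#'   table.
#' @return validated object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 249,
                          prevalence = c(SIRS = 106, indeterminate = 74,
                                         sepsis = 69) / 249,
                          rater_confusion = default_rater_confusion(),
                          covariate_params = default_covariate_params(),
                          site_distribution = default_site_distribution(),
                          antibiotic_model = default_antibiotic_model(),
                          antibiotic_class_offset = c(SIRS = 0,
                                                      indeterminate = 2.25,
                                                      sepsis = Inf),
                          missingness = default_missingness(),
                          hospital_labels = default_hospitals(),
                          shared_difficulty = 0,
                          rpd_follows_discharge = 0,
                          multi_site_prob = 0.005,
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients, prevalence = prevalence,
         rater_confusion = rater_confusion,
         covariate_params = covariate_params,
         site_distribution = site_distribution,
         antibiotic_model = antibiotic_model,
         antibiotic_class_offset = antibiotic_class_offset,
         missingness = missingness, hospital_labels = hospital_labels,
         shared_difficulty = shared_difficulty,
         rpd_follows_discharge = rpd_follows_discharge,
         multi_site_prob = multi_site_prob, seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(config$n_patients) || config$n_patients < 1) {
    stop("invalid field 'n_patients': must be a positive count", call. = FALSE)
  }
  pv <- config$prevalence
  if (length(pv) != 3 || !setequal(names(pv), category_levels())) {
    stop("invalid field 'prevalence': must be named over SIRS/indeterminate/sepsis",
         call. = FALSE)
  }
  if (abs(sum(pv) - 1) > 1e-12 || any(pv < 0)) {
    stop("invalid field 'prevalence': must be non-negative and sum to 1",
         call. = FALSE)
  }
  roles <- evaluator_roles()
  if (!all(roles %in% names(config$rater_confusion))) {
    stop("invalid field 'rater_confusion': missing role(s) ",
         paste(setdiff(roles, names(config$rater_confusion)), collapse = ", "),
         call. = FALSE)
  }
  for (r in roles) {
    m <- config$rater_confusion[[r]]
    if (!is.matrix(m) || !all(dim(m) == c(3, 4)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-12)) {
      stop("invalid field 'rater_confusion': matrix for role '", r,
           "' is not 3x4 row-stochastic", call. = FALSE)
    }
  }
  sd_ <- config$site_distribution
  if (!is.matrix(sd_) || !all(dim(sd_) == c(3, length(site_levels()))) ||
      any(sd_ < 0) || any(abs(rowSums(sd_) - 1) > 1e-12)) {
    stop("invalid field 'site_distribution': must be 3x", length(site_levels()),
         " row-stochastic", call. = FALSE)
  }
  if (any(config$missingness < 0) || any(config$missingness >= 1)) {
    stop("invalid field 'missingness': fractions must lie in [0, 1)",
         call. = FALSE)
  }
  if (config$shared_difficulty < 0 ||
      config$rpd_follows_discharge < 0 || config$rpd_follows_discharge > 1) {
    stop("invalid field 'shared_difficulty'/'rpd_follows_discharge': out of range",
         call. = FALSE)
  }
  if (!inherits(config$antibiotic_model, "logistic_model_spec")) {
    stop("invalid field 'antibiotic_model': must be a logistic_model_spec",
         call. = FALSE)
  }
  invisible(config)
}
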