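# Published class-conditional probability tables used as generative defaults.
# Printed columns that do not sum to exactly 1 (rounding in print) are
# renormalized at load.

engagement_class_names <- function() {
  c("super", "medium", "wt_consistent", "wt_almost", "wt_inconsistent",
    "non_user")
}

subgroup_class_names <- function() {
  c("black_young", "black_heavier", "hispanic", "white")
}

rho_matrix <- function(values, classes, levels) {
  m <- matrix(values, nrow = length(classes), byrow = TRUE,
              dimnames = list(classes, levels))
  m / rowSums(m)
}

#' Reference parameters of the six engagement-pattern classes
#'
#' Class prevalences and class-conditional item-response probabilities for the
#' six engagement patterns (super-users, medium-users, consistent /
#' almost-consistent / inconsistent weight-tracker users, and non-users).
#' These are the default generative truth of [generator_config()] and the
#' reference against which parameter-recovery checks align fitted models.
#'
#' @return A list with elements `gamma` (named length-6 prevalence vector,
#'   summing to 1), `rho` (named list of class-by-level probability matrices,
#'   one per indicator of [engagement_spec()]) and `spec`.
#' @export
engagement_params <- function() {
  cls <- engagement_class_names()
  spec <- engagement_spec()
  gamma <- c(0.1302, 0.1400, 0.1499, 0.2199, 0.1598, 0.2002)
  names(gamma) <- cls
  rho <- list(
    login = rho_matrix(c(
      0.93, 0.07, 0.00, 0.00,
      0.12, 0.86, 0.02, 0.00,
      0.97, 0.03, 0.00, 0.00,
      0.14, 0.84, 0.01, 0.00,
      0.04, 0.08, 0.89, 0.00,
      0.00, 0.02, 0.34, 0.64), cls, spec$levels$login),
    weight_tracker = rho_matrix(c(
      0.88, 0.11, 0.01, 0.00,
      0.00, 0.85, 0.13, 0.02,
      0.83, 0.13, 0.01, 0.03,
      0.02, 0.63, 0.28, 0.08,
      0.00, 0.00, 0.71, 0.29,
      0.00, 0.00, 0.00, 1.00), cls, spec$levels$weight_tracker),
    health_info = rho_matrix(c(
      0.84, 0.16, 0.00,
      0.65, 0.27, 0.09,
      0.23, 0.42, 0.35,
      0.08, 0.31, 0.61,
      0.06, 0.20, 0.73,
      0.00, 0.01, 0.99), cls, spec$levels$health_info),
    blogs = rho_matrix(c(
      0.91, 0.07, 0.01,
      0.59, 0.31, 0.09,
      0.24, 0.44, 0.32,
      0.09, 0.43, 0.48,
      0.08, 0.33, 0.59,
      0.00, 0.01, 1.00), cls, spec$levels$blogs),
    resources = rho_matrix(c(
      0.89, 0.11, 0.00,
      0.47, 0.27, 0.25,
      0.06, 0.33, 0.61,
      0.01, 0.20, 0.79,
      0.05, 0.16, 0.80,
      0.00, 0.00, 1.00), cls, spec$levels$resources),
    pa_goal = rho_matrix(c(
      0.53, 0.17, 0.30,
      0.45, 0.21, 0.33,
      0.18, 0.14, 0.67,
      0.02, 0.14, 0.84,
      0.04, 0.20, 0.76,
      0.00, 0.00, 1.00), cls, spec$levels$pa_goal),
    diet_goal = rho_matrix(c(
      0.50, 0.16, 0.34,
      0.42, 0.20, 0.38,
      0.17, 0.18, 0.65,
      0.05, 0.15, 0.80,
      0.10, 0.20, 0.70,
      0.00, 0.00, 1.00), cls, spec$levels$diet_goal)
  )
  list(gamma = gamma / sum(gamma), rho = rho[spec$items], spec = spec)
}

#' Reference parameters of the four demographic/BMI subgroups
#'
#' Class prevalences and class-conditional response probabilities for the
#' four person-centered demographic/BMI subgroups (black-young, black-heavier,
#' Hispanic, white). Defaults of the synthetic roster generator and the
#' reference truth for subgroup-model recovery checks.
#'
#' @return A list with elements `gamma`, `rho` and `spec`
#'   (see [engagement_params()]).
#' @export
subgroup_params <- function() {
  cls <- subgroup_class_names()
  spec <- subgroup_spec()
  gamma <- c(0.2051, 0.1302, 0.1154, 0.5493)
  names(gamma) <- cls
  rho <- list(
    race = rho_matrix(c(
      0.29, 0.71, 0.00,
      0.42, 0.56, 0.01,
      0.02, 0.01, 0.96,
      0.94, 0.00, 0.06), cls, spec$levels$race),
    ethnicity = rho_matrix(c(
      0.06, 0.94,
      0.04, 0.96,
      0.84, 0.16,
      0.02, 0.98), cls, spec$levels$ethnicity),
    low_income = rho_matrix(c(
      0.89, 0.11,
      0.67, 0.33,
      0.78, 0.22,
      0.11, 0.89), cls, spec$levels$low_income),
    bmi_cat = rho_matrix(c(
      0.67, 0.20, 0.13,
      0.12, 0.45, 0.43,
      0.41, 0.41, 0.18,
      0.60, 0.27, 0.12), cls, spec$levels$bmi_cat),
    age_cat = rho_matrix(c(
      0.82, 0.14, 0.03,
      0.23, 0.49, 0.28,
      0.55, 0.31, 0.15,
      0.07, 0.34, 0.59), cls, spec$levels$age_cat)
  )
  list(gamma = gamma / sum(gamma), rho = rho[spec$items], spec = spec)
}
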