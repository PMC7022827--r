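#' Published study estimates
#'
#' The fitted values reported by the indigo-blue / *Spirulina platensis*
#' biosorption study, exposed as tibbles built in code. They serve two
#' roles: generating truths for the synthetic-data generators (parameter
#' recovery closes the loop against the published estimates), and
#' reference rows for report layouts.
#'
#' * `study_kinetic_estimates()` — per initial concentration, the
#'   one-parameter first-order rate constant `K1` (1/h) and Ho
#'   second-order rate constant `k2` (L/(mg h)) with their standard
#'   errors, residual errors and MSC values.
#' * `study_isotherm_estimates()` — per temperature, the through-origin
#'   isotherm slope `b_o` (L/g) with SE, p-value and R-squared.
#' * `study_equilibrium_summary()` — per initial concentration, the
#'   expected equilibrium adsorption (91% of `Ci`) and the observed mean
#'   with its 95% half-width.
#'
#' @return A tibble.
#' @name study-estimates
NULL

#' @rdname study-estimates
#' @export
study_kinetic_estimates <- function() {
  tibble(
    ci_mg_per_L = c(25, 50, 75, 100),
    k1_per_h = c(0.046, 0.052, 0.047, 0.067),
    k1_se = c(0.0047, 0.0027, 0.0081, 0.015),
    k1_residual = c(1.146, 0.993, 5.64, 8.774),
    k1_msc = c(5.10, 6.03, 4.60, 4.14),
    k2_L_per_mg_h = c(0.00265, 0.00180, 0.00088, 0.00095),
    k2_se = c(0.00050, 0.00013, 0.00022, 0.00021),
    k2_residual = c(1.954, 1.128, 7.648, 8.722),
    k2_msc = c(4.15, 5.79, 4.02, 4.15)
  )
}

#' @rdname study-estimates
#' @export
study_isotherm_estimates <- function() {
  tibble(
    temperature_C = c(30, 40, 50),
    b_o = c(0.260, 3.104, 10.220),
    b_o_se = c(0.047, 0.1622, 0.500),
    p_value = c(0.011, 0.001, 0.001),
    r_squared = c(0.883, 0.987, 0.988)
  )
}

#' @rdname study-estimates
#' @export
study_equilibrium_summary <- function() {
  tibble(
    ci_mg_per_L = c(25, 50, 75, 100),
    expected_qe_mg_per_L = c(22.8, 45.5, 68.3, 91),
    observed_qe_mg_per_L = c(23.1, 45.4, 67.7, 89.9),
    ci95_halfwidth = c(0.3, 2.3, 4.5, 7.21)
  )
}
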