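#' Monte-Carlo parameter-recovery simulations
#'
#' Validation protocols that close the loop between the synthetic-data
#' generators and the fitters: repeatedly generate a dataset from a known
#' truth under the study's experimental design, refit it, and return the
#' estimates. The mean recovered estimate is compared against the
#' generating truth (for an unbiased estimator it should sit well within
#' the estimator's standard error).
#'
#' @param seed Integer seed; replication `i` draws from an independent
#'   stream derived from `(seed, i)`.
#' @param ci Initial concentration, mg/L.
#' @param model Generating kinetic model, `"first_order"` or
#'   `"second_order"`.
#' @param rate Generating rate constant.
#' @param n_reps Number of replications.
#' @param noise_sd Gaussian noise sd on the generated observable.
#' @param ... Further arguments to [generate_time_course()].
#' @return Numeric vector of `n_reps` recovered rate constants.
#' @examples
#' k1s <- simulate_kinetic_recovery(1, ci = 50, rate = 0.052, n_reps = 20)
#' mean(k1s)
#' @export
simulate_kinetic_recovery <- function(seed, ci = 50,
                                      model = c("first_order", "second_order"),
                                      rate = 0.052, n_reps = 500,
                                      noise_sd = 1, ...) {
  model <- match.arg(model)
  fit1 <- function(i) {
    tc <- generate_time_course(seed, ci = ci, model = model, rate = rate,
                               noise_sd = noise_sd,
                               stream = paste0("recovery/", i), ...)
    if (model == "first_order") fit_first_order(tc)$rate_constant
    else fit_second_order(tc)$rate_constant
  }
  vapply(seq_len(n_reps), fit1, numeric(1))
}

#' @rdname simulate_kinetic_recovery
#' @param b_o Generating through-origin isotherm slope, L/g.
#' @param temperature_C Temperature label for the generated datasets.
#' @return `simulate_isotherm_recovery()`: numeric vector of `n_reps`
#'   recovered slopes.
#' @export
simulate_isotherm_recovery <- function(seed, b_o = 10.22, n_reps = 200,
                                       noise_sd = 0.5, temperature_C = 50) {
  vapply(seq_len(n_reps), function(i) {
    iso <- generate_isotherm(seed, b_o = b_o, noise_sd = noise_sd,
                             temperature_C = temperature_C,
                             stream = paste0("recovery/", i))
    fit_linear_origin(iso)$slope
  }, numeric(1))
}
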