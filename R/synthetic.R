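#' Seeded synthetic-data generators
#'
#' Generators that emulate the statistical structure of the study's four
#' experimental designs (pH screen, kinetic time courses, equilibrium
#' isotherms, calibration series) so that every pipeline stage can be
#' exercised and validated by Monte-Carlo parameter recovery. Noise is
#' additive Gaussian on the measured observable, truncated at zero;
#' truncation events are counted and carried on the result so silent
#' distribution distortion is visible.
#'
#' One global integer `seed` drives a named random stream per design
#' (plus any caller-supplied `stream` suffix), so generating one design
#' never perturbs another and identical configurations reproduce
#' bit-identical data.
#'
#' @name synthetic-data
NULL

#' Generate a synthetic kinetic time course
#'
#' Truth curve from the named kinetic model, additive Gaussian noise per
#' replicate observation, floored at zero with a truncation count. The
#' default design matches the study: sampling at 0, 24, 48, 72, 96 h in
#' triplicate. First-order truth is generated in adsorbed space (the
#' fixed-Qe Lagergren curve, `value_kind = "adsorbed"`), second-order
#' truth in remaining-concentration space.
#'
#' @param seed Integer seed.
#' @param ci Initial concentration, mg/L.
#' @param model `"first_order"` or `"second_order"`.
#' @param rate Generating rate constant (`K1` in 1/h, or `k2` in
#'   L/(mg h)).
#' @param times Sampling times, h. Default `c(0, 24, 48, 72, 96)`.
#' @param n_replicates Replicates per time point. Default 3.
#' @param noise_sd Gaussian noise sd in the units of the generated
#'   observable (mg/L or mg/g). Default 1.0, the residual scale of the
#'   study's kinetic fits at 50 mg/L.
#' @param equilibrium_fraction Fixed equilibrium fraction for the
#'   first-order truth. Default 0.91.
#' @param stream Extra stream suffix to decorrelate repeated calls at
#'   one seed (e.g. a replication index).
#' @return A [time_course()]; attribute `truncated` counts floored
#'   observations.
#' @export
generate_time_course <- function(seed, ci = 50,
                                 model = c("first_order", "second_order"),
                                 rate = 0.052,
                                 times = c(0, 24, 48, 72, 96),
                                 n_replicates = 3, noise_sd = 1,
                                 equilibrium_fraction = 0.91,
                                 stream = "") {
  model <- match.arg(model)
  check_scalar_number(noise_sd, "noise_sd", 0)
  check_scalar_number(n_replicates, "n_replicates", 1)
  truth <- switch(model,
    first_order = first_order_adsorbed(ci, rate, times, equilibrium_fraction),
    second_order = second_order_remaining(ci, rate, times)
  )
  grid <- tidyr::expand_grid(time_h = times, replicate = seq_len(n_replicates))
  truth_all <- truth[match(grid$time_h, times)]
  # t = 0 is the prepared initial condition, not a back-calculated
  # measurement: it carries no noise (and no information about the rate,
  # whose model gradient vanishes there).
  measured <- grid$time_h > 0
  noisy <- with_stream_seed(seed, paste0("time_course/", stream), {
    truth_all + rnorm(nrow(grid), sd = noise_sd) * measured
  })
  truncated <- sum(noisy < 0)
  grid$value <- pmax(noisy, 0)
  suppressWarnings(time_course(
    grid, ci = ci,
    value_kind = if (model == "first_order") "adsorbed" else "remaining",
    ph = 4, temperature_C = 25, truncated = truncated
  ))
}

#' Generate a synthetic equilibrium isotherm
#'
#' Truth per initial concentration from the C-type partitioning law:
#' `Ce = Ci / (1 + b_o * B)`, `qe = b_o * Ce`; Gaussian noise on `qe`.
#'
#' @inheritParams generate_time_course
#' @param b_o Generating through-origin slope, L/g (> 0 unless exactly 0
#'   for a no-adsorption control).
#' @param ci Initial concentrations, mg/L. Default the study design
#'   `c(6.25, 12.5, 25, 50, 100)`.
#' @param biomass Biosorbent concentration, g/L. Default 1.
#' @param temperature_C Temperature metadata.
#' @param noise_sd Gaussian sd on `qe`, mg/g. Default 0.5.
#' @return An [build_isotherm()] dataset.
#' @export
generate_isotherm <- function(seed, b_o = 10.22,
                              ci = c(6.25, 12.5, 25, 50, 100),
                              biomass = 1, temperature_C = 50,
                              noise_sd = 0.5, stream = "") {
  check_scalar_number(b_o, "b_o", 0)
  ce_truth <- ci / (1 + b_o * biomass)
  qe_truth <- b_o * ce_truth
  qe <- with_stream_seed(seed, paste0("isotherm/", stream), {
    qe_truth + rnorm(length(ci), sd = noise_sd)
  })
  # noise sits on the measured qe only; Ce keeps its equilibrium truth,
  # so the mass balance Ce + qe*B = Ci no longer closes exactly — the
  # residual is recorded rather than forced shut
  out <- tibble(ci_mg_per_L = ci, ce_mg_per_L = ce_truth, qe_mg_per_g = qe)
  structure(out,
            class = c("isotherm_dataset", class(out)),
            biomass_g_per_L = biomass, temperature_C = temperature_C,
            mass_balance_residual = ci - ce_truth - qe * biomass)
}

#' Generate a synthetic pH screen
#'
#' Unimodal removal-vs-pH profile. The study reports only the location
#' and height of the optimum (pH 4, 46.84% removal at 50 mg/L after
#' 24 h), so the profile shape is an invention of this generator: a
#' Gaussian in pH centred on the peak, a width of 1.5 pH units, replicate
#' Gaussian noise. The noiseless profile's argmax equals the configured
#' peak by construction.
#'
#' @inheritParams generate_time_course
#' @param ph_grid pH levels screened. Default `4:10`.
#' @param peak_ph Location of the optimum (must lie on the grid).
#' @param peak_removal Removal percent at the optimum. Default 46.84.
#' @param width Gaussian width in pH units. Default 1.5.
#' @param noise_sd Replicate noise sd in percentage points. Default 2.
#' @return A tibble `ph`, `replicate`, `removal_percent`, plus the
#'   noiseless `truth_percent`.
#' @export
generate_ph_screen <- function(seed, ph_grid = 4:10, peak_ph = 4,
                               peak_removal = 46.84, width = 1.5,
                               n_replicates = 3, noise_sd = 2,
                               stream = "") {
  if (!peak_ph %in% ph_grid) {
    abort("`peak_ph` must lie on `ph_grid`.", class = "biosorb_config_error")
  }
  truth <- peak_removal * exp(-(ph_grid - peak_ph)^2 / (2 * width^2))
  grid <- tidyr::expand_grid(ph = ph_grid, replicate = seq_len(n_replicates))
  grid$truth_percent <- truth[match(grid$ph, ph_grid)]
  grid$removal_percent <- with_stream_seed(seed, paste0("ph_screen/", stream), {
    grid$truth_percent + rnorm(nrow(grid), sd = noise_sd)
  })
  grid[c("ph", "replicate", "removal_percent", "truth_percent")]
}

#' Generate synthetic calibration standards
#'
#' Optical densities from the linear standard curve (default: the
#' published curve OD = 0.003 C + 0.0348 over 50-800 mg/L) with Gaussian
#' OD noise.
#'
#' @inheritParams generate_time_course
#' @param concentrations Standard concentrations, mg/L. Default
#'   `seq(50, 800, by = 50)`.
#' @param slope,intercept Generating line. Defaults 0.003, 0.0348.
#' @param noise_sd OD noise sd. Default 0.005.
#' @return A tibble `concentration_mg_per_L`, `od`.
#' @export
generate_calibration <- function(seed,
                                 concentrations = seq(50, 800, by = 50),
                                 slope = 0.003, intercept = 0.0348,
                                 noise_sd = 0.005, stream = "") {
  check_scalar_number(slope, "slope", 0, strict_min = TRUE)
  od <- with_stream_seed(seed, paste0("calibration/", stream), {
    slope * concentrations + intercept +
      rnorm(length(concentrations), sd = noise_sd)
  })
  tibble(concentration_mg_per_L = concentrations, od = od)
}

#' Generate a complete synthetic study
#'
#' Materialises one synthetic analogue of the whole study from a single
#' seed: calibration series, pH screen, four kinetic time courses
#' (Ci = 25, 50, 75, 100 mg/L, first-order truths from the published
#' kinetic estimates) and three isotherms (30, 40, 50 degC, slopes from
#' the published isotherm fits).
#'
#' @param seed Integer seed.
#' @param noise_sd_kinetics,noise_sd_isotherm Noise levels passed on.
#' @return A named list: `calibration`, `ph_screen`, `time_courses`
#'   (named by Ci), `isotherms` (named by temperature).
#' @export
generate_study <- function(seed, noise_sd_kinetics = 1,
                           noise_sd_isotherm = 0.5) {
  kin <- study_kinetic_estimates()
  iso <- study_isotherm_estimates()
  list(
    calibration = generate_calibration(seed),
    ph_screen = generate_ph_screen(seed),
    time_courses = setNames(
      purrr::map2(kin$ci_mg_per_L, kin$k1_per_h, function(ci, k1) {
        generate_time_course(seed, ci = ci, model = "first_order",
                             rate = k1, noise_sd = noise_sd_kinetics,
                             stream = paste0("ci", ci))
      }),
      kin$ci_mg_per_L
    ),
    isotherms = setNames(
      purrr::map2(iso$temperature_C, iso$b_o, function(temp, b) {
        generate_isotherm(seed, b_o = b, temperature_C = temp,
                          noise_sd = noise_sd_isotherm,
                          stream = paste0("T", temp))
      }),
      iso$temperature_C
    )
  )
}

#' Write a synthetic study to CSV fixtures
#'
#' Materialises [generate_study()] in the CSV dialects the analysis
#' readers consume: `calibration.csv`, `ph_screen.csv`,
#' `time_course_ci<Ci>.csv` per concentration, `isotherms.csv`.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_fixtures <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(seed)
  readr::write_csv(study$calibration, file.path(dir, "calibration.csv"))
  readr::write_csv(study$ph_screen, file.path(dir, "ph_screen.csv"))
  purrr::iwalk(study$time_courses, function(tc, ci) {
    write_time_course_csv(tc, file.path(dir, paste0("time_course_ci", ci, ".csv")))
  })
  write_isotherm_csv(study$isotherms, file.path(dir, "isotherms.csv"))
  invisible(dir)
}
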