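#' Summarise equilibrium adsorption across time courses
#'
#' Builds the equilibrium summary table: per initial concentration, the
#' expected equilibrium adsorption `Qe = equilibrium_fraction * Ci`
#' against the observed mean adsorption over the late samples (times >=
#' `min_time_h`, once the process has plateaued), with a 95% Student-t
#' interval computed on the replicate means.
#'
#' @param time_courses A list of [time_course()] objects, each spanning
#'   at least `min_time_h`.
#' @param equilibrium_fraction Expected equilibrium fraction of `Ci`.
#'   Default 0.91.
#' @param min_time_h Samples at or after this time count as equilibrium
#'   observations. Default 72 h (day 3 onward).
#' @return A tibble: `ci_mg_per_L`, `expected_qe_mg_per_L`,
#'   `observed_qe_mg_per_L`, `ci95_halfwidth`, `observed_fraction`,
#'   `n_replicates`.
#' @export
summarize_equilibrium <- function(time_courses, equilibrium_fraction = 0.91,
                                  min_time_h = 72) {
  purrr::map(time_courses, function(tc) {
    stopifnot(inherits(tc, "time_course"))
    late <- tc$time_h >= min_time_h
    if (!any(late)) {
      abort("Time course has no observations at or after `min_time_h`.",
            class = "biosorb_degenerate_input")
    }
    ci <- tc_ci(tc)
    q <- tc_adsorbed(tc)[late]
    reps <- tc$replicate[late]
    rep_means <- tapply(q, reps, mean)
    n <- length(rep_means)
    obs <- mean(rep_means)
    half <- if (n > 1) qt(0.975, df = n - 1) * sd(rep_means) / sqrt(n) else NA_real_
    tibble(
      ci_mg_per_L = ci,
      expected_qe_mg_per_L = equilibrium_fraction * ci,
      observed_qe_mg_per_L = obs,
      ci95_halfwidth = half,
      observed_fraction = obs / ci,
      n_replicates = n
    )
  }) |>
    dplyr::bind_rows()
}

#' Run the full biosorption analysis pipeline
#'
#' Orchestrates every stage — calibration, pH screen summary, kinetic
#' fits of both models with MSC comparison, equilibrium summary, and
#' isotherm fits — and emits a machine-readable report. Inputs come
#' either from CSV files named in the configuration or, with
#' `synthetic = TRUE`, from [generate_study()] at the configured seed.
#'
#' The configuration is a list (or a YAML/JSON file path) with fields:
#' `synthetic` (logical), `seed` (integer), `equilibrium_fraction`
#' (default 0.91), `output_dir` (optional; when set, `report.json`,
#' `table2_equilibrium.csv`, `table3_kinetics.csv` and
#' `table4_isotherms.csv` are written there), and under `inputs` the CSV
#' paths `calibration`, `ph_screen`, `time_courses` (character vector),
#' `isotherms`. Re-running an identical configuration rewrites identical
#' outputs.
#'
#' A fit failure in one stage is recorded in the report's `errors` block
#' without aborting the remaining stages.
#'
#' @param config A list or path to a YAML/JSON configuration file.
#' @return A `study_report`: list with elements `calibration`,
#'   `ph_screen`, `equilibrium`, `kinetics`, `isotherms`, `errors`, and
#'   a `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- modifyList(
    list(synthetic = FALSE, seed = 1L, equilibrium_fraction = 0.91,
         output_dir = NULL, inputs = list()),
    config
  )
  errors <- list()
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  if (isTRUE(cfg$synthetic)) {
    study <- generate_study(cfg$seed)
  } else {
    study <- tryCatch(load_study_inputs(cfg$inputs),
                      error = function(e) {
                        abort(paste0("input: ", conditionMessage(e)),
                              class = "biosorb_input_error")
                      })
  }

  calib <- tryCatch(fit_calibration(study$calibration),
                    error = function(e) note_error("calibration", e))

  ph_summary <- tryCatch(
    study$ph_screen |>
      dplyr::group_by(.data$ph) |>
      dplyr::summarise(removal_percent = mean(.data$removal_percent),
                       .groups = "drop"),
    error = function(e) note_error("ph_screen", e)
  )

  kinetics <- purrr::imap(study$time_courses, function(tc, nm) {
    tryCatch({
      fo <- fit_first_order(tc, cfg$equilibrium_fraction)
      so <- fit_second_order(tc)
      cmp <- suppressWarnings(compare_kinetic_models(tc, fo, so))
      list(first_order = fo, second_order = so, comparison = cmp)
    }, error = function(e) note_error(paste0("kinetics_ci", nm), e))
  })

  equilibrium <- tryCatch(
    summarize_equilibrium(study$time_courses, cfg$equilibrium_fraction),
    error = function(e) note_error("equilibrium", e)
  )

  isotherms <- purrr::imap(study$isotherms, function(d, nm) {
    tryCatch(fit_linear_origin(d),
             error = function(e) note_error(paste0("isotherm_", nm), e))
  })

  report <- structure(
    list(
      calibration = calib,
      ph_screen = ph_summary,
      equilibrium = equilibrium,
      kinetics = kinetics,
      isotherms = isotherms,
      errors = errors,
      provenance = list(
        # hash of the analysis-relevant configuration; the output
        # location does not change the analysis
        config_hash = rlang::hash(cfg[setdiff(names(cfg), "output_dir")]),
        seed = cfg$seed,
        synthetic = isTRUE(cfg$synthetic),
        package_version = as.character(utils::packageVersion("biosorb")),
        schema_version = "1.0"
      )
    ),
    class = "study_report"
  )
  if (!is.null(cfg$output_dir)) write_study_report(report, cfg$output_dir)
  report
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "biosorb_input_error")
  }
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

load_study_inputs <- function(inputs) {
  need <- c("calibration", "ph_screen", "time_courses", "isotherms")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    abort(paste0("Missing input path(s): ", paste(missing, collapse = ", ")),
          class = "biosorb_input_error")
  }
  list(
    calibration = read_calibration_csv(inputs$calibration),
    ph_screen = readr::read_csv(inputs$ph_screen, col_types = readr::cols()),
    time_courses = purrr::map(inputs$time_courses, read_time_course_csv) |>
      setNames(vapply(purrr::map(inputs$time_courses, read_time_course_csv),
                      tc_ci, numeric(1))),
    isotherms = read_isotherm_csv(inputs$isotherms)
  )
}

#' Tabular views of a study report
#'
#' `kinetics_table()` mirrors the study's model-comparison layout (one
#' row per initial concentration and model: estimate, SE, RMSE, RSE,
#' MSC); `isotherm_table()` its isotherm layout (temperature, slope, SE,
#' p, R-squared, implied removal fraction).
#'
#' @param report A `study_report` from [run_pipeline()].
#' @return A tibble.
#' @export
kinetics_table <- function(report) {
  purrr::imap(report$kinetics, function(k, nm) {
    if (is.null(k)) return(NULL)
    dplyr::mutate(as_tibble(k$comparison), ci_mg_per_L = as.numeric(nm),
                  .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' @rdname kinetics_table
#' @export
isotherm_table <- function(report) {
  purrr::map(report$isotherms, function(f) {
    if (is.null(f)) return(NULL)
    dplyr::bind_cols(
      tibble(temperature_C = f$temperature_C),
      tidy(f)[c("estimate", "std.error", "p.value")],
      tibble(r_squared = f$r_squared,
             implied_removal_fraction =
               implied_removal_fraction(f$slope, f$biomass_g_per_L %||% 1))
    )
  }) |>
    dplyr::bind_rows()
}

#' Write a study report to disk
#'
#' Emits `report.json` plus the three per-stage CSV tables
#' (`table2_equilibrium.csv`, `table3_kinetics.csv`,
#' `table4_isotherms.csv`). Deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eq <- report$equilibrium
  kin <- kinetics_table(report)
  iso <- isotherm_table(report)
  if (!is.null(eq)) readr::write_csv(eq, file.path(dir, "table2_equilibrium.csv"))
  if (nrow(kin)) readr::write_csv(kin, file.path(dir, "table3_kinetics.csv"))
  if (nrow(iso)) readr::write_csv(iso, file.path(dir, "table4_isotherms.csv"))
  json <- list(
    calibration = if (!is.null(report$calibration)) list(
      slope = report$calibration$slope,
      intercept = report$calibration$intercept,
      r_squared = report$calibration$r_squared,
      n_points = report$calibration$n_points
    ),
    ph_screen = report$ph_screen,
    equilibrium = eq,
    kinetics = kin,
    isotherms = iso,
    errors = report$errors,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Biosorption study report (seed", x$provenance$seed,
      if (x$provenance$synthetic) ", synthetic" else "", ")\n", sep = "")
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$equilibrium)) {
    cat("\nEquilibrium summary:\n"); print(x$equilibrium)
  }
  kin <- kinetics_table(x)
  if (nrow(kin)) { cat("\nKinetic model comparison:\n"); print(kin) }
  iso <- isotherm_table(x)
  if (nrow(iso)) { cat("\nIsotherm fits:\n"); print(iso) }
  if (length(x$errors)) {
    cat("\nStage errors:\n")
    purrr::iwalk(x$errors, ~ cat("  ", .y, ": ", .x, "\n", sep = ""))
  }
  invisible(x)
}
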