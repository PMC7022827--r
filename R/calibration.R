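#' Fit a linear optical-density calibration curve
#'
#' Dye concentrations are quantified spectrophotometrically: a standard
#' series of known concentrations is measured and the optical density (OD)
#' is regressed linearly on concentration, `OD = m * C + b`. The fitted
#' line is later inverted to back-calculate unknown concentrations from OD
#' readings with [od_to_concentration()].
#'
#' @param points A data frame with columns `concentration_mg_per_L` and
#'   `od` (one row per standard).
#' @param wavelength_nm Measurement wavelength, carried as metadata only
#'   (never used in computation). Default 600 nm.
#'
#' @return An object of class `calibration_curve`: a list with `slope`
#'   (OD per mg/L), `intercept` (OD), `r_squared` (centred coefficient of
#'   determination), `n_points`, `wavelength_nm`, and the underlying `lm`
#'   fit.
#'
#' @examples
#' std <- tibble::tibble(
#'   concentration_mg_per_L = seq(50, 800, by = 50),
#'   od = 0.003 * concentration_mg_per_L + 0.0348
#' )
#' fit_calibration(std)
#' @export
fit_calibration <- function(points, wavelength_nm = 600) {
  stopifnot(is.data.frame(points))
  req <- c("concentration_mg_per_L", "od")
  if (!all(req %in% names(points))) {
    abort(paste0("`points` needs columns: ", paste(req, collapse = ", ")),
          class = "biosorb_invalid_input")
  }
  conc <- points$concentration_mg_per_L
  od <- points$od
  if (length(unique(conc)) < 2) {
    abort("Calibration needs at least 2 distinct concentrations.",
          class = "biosorb_degenerate_input")
  }
  fit <- lm(od ~ conc)
  tss <- sum((od - mean(od))^2)
  rss <- sum(fit$residuals^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n_points = length(od),
      wavelength_nm = wavelength_nm,
      lm_fit = fit
    ),
    class = "calibration_curve"
  )
}

#' Convert between optical density and concentration
#'
#' `od_to_concentration()` inverts the calibration line, `(od - b) / m`;
#' `concentration_to_od()` evaluates it forward (used by the synthetic
#' generator). Back-calculated concentrations below zero are reported
#' as-is with a warning by default — silent clamping would hide
#' calibration drift — but can be clamped with `clamp_negative = TRUE`.
#'
#' @param od,concentration Numeric vectors.
#' @param curve A `calibration_curve` from [fit_calibration()], or any
#'   list with `slope` and `intercept`.
#' @param clamp_negative If `TRUE`, negative back-calculated
#'   concentrations are set to 0. Default `FALSE`.
#' @return Numeric vector (mg/L for the inverse map, OD forward).
#' @examples
#' curve <- list(slope = 0.003, intercept = 0.0348)
#' od_to_concentration(0.3348, curve)  # 100 mg/L
#' @export
od_to_concentration <- function(od, curve, clamp_negative = FALSE) {
  if (!is.numeric(curve$slope) || curve$slope == 0) {
    abort("Calibration curve has zero slope; inversion undefined.",
          class = "biosorb_invalid_curve")
  }
  conc <- (od - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    if (clamp_negative) {
      conc <- pmax(conc, 0)
    } else {
      warn("Negative back-calculated concentration(s); reported as-is.",
           class = "biosorb_negative_concentration")
    }
  }
  conc
}

#' @rdname od_to_concentration
#' @export
concentration_to_od <- function(concentration, curve) {
  curve$slope * concentration + curve$intercept
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve: OD =",
      format(x$slope, digits = 6), "* C +",
      format(x$intercept, digits = 6), "\n")
  cat("  R-squared:", format(x$r_squared, digits = 6),
      " n =", x$n_points,
      " wavelength:", x$wavelength_nm, "nm\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  s <- summary(x$lm_fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points,
         wavelength_nm = x$wavelength_nm)
}

#' Read calibration standards / write a fitted curve
#'
#' The calibration CSV dialect has header `concentration_mg_per_L,od`.
#' The fitted curve is serialised as JSON with fields `slope`,
#' `intercept`, `r_squared`, `n_points`.
#'
#' @param path File path.
#' @param curve A `calibration_curve`.
#' @return `read_calibration_csv()` returns a tibble;
#'   `write_calibration_json()` returns `path` invisibly.
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    concentration_mg_per_L = readr::col_double(),
    od = readr::col_double()
  ))
}

#' @rdname read_calibration_csv
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         r_squared = curve$r_squared, n_points = curve$n_points),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
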