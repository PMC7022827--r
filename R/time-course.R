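#' Construct a kinetic time course
#'
#' A `time_course` is a tidy tibble of one kinetic experiment — replicate
#' measurements of remaining concentration (or adsorbed amount) over time
#' at one initial dye concentration — with the experiment-level metadata
#' (initial concentration, pH, temperature) held as attributes.
#'
#' @param data A data frame with columns `time_h`, `replicate`, `value`.
#'   Times must include 0 and, per sampling occasion, be shared across
#'   replicates; values must be finite.
#' @param ci Initial concentration, mg/L (> 0).
#' @param value_kind `"remaining"` (Ct, mg/L) or `"adsorbed"` (q, mg/g at
#'   the 1 g/L biomass convention).
#' @param ph,temperature_C Experimental metadata (optional).
#' @param truncated Count of generator observations floored at zero
#'   (bookkeeping from [generate_time_course()]).
#' @return A tibble of class `time_course`.
#' @export
time_course <- function(data, ci, value_kind = c("remaining", "adsorbed"),
                        ph = NA_real_, temperature_C = NA_real_,
                        truncated = 0L) {
  value_kind <- match.arg(value_kind)
  check_scalar_number(ci, "ci", 0, strict_min = TRUE)
  stopifnot(is.data.frame(data),
            all(c("time_h", "replicate", "value") %in% names(data)))
  times <- sort(unique(data$time_h))
  if (times[1] != 0) {
    abort("Time course must include t = 0.", class = "biosorb_invalid_input")
  }
  if (any(!is.finite(data$value))) {
    abort("Non-finite values in time course.", class = "biosorb_invalid_input")
  }
  if (any(data$value < 0)) {
    warn("Negative values in time course; kept and flagged.",
         class = "biosorb_negative_values")
  }
  out <- as_tibble(data[c("time_h", "replicate", "value")])
  out <- dplyr::arrange(out, .data$time_h, .data$replicate)
  structure(out,
            class = c("time_course", class(out)),
            ci = ci, value_kind = value_kind, ph = ph,
            temperature_C = temperature_C, truncated = truncated)
}

tc_ci <- function(tc) attr(tc, "ci")
tc_kind <- function(tc) attr(tc, "value_kind")

# Observed series in adsorbed space (q, mg/g at B = 1 g/L).
tc_adsorbed <- function(tc) {
  if (tc_kind(tc) == "adsorbed") tc$value else tc_ci(tc) - tc$value
}

# Observed series in remaining-concentration space (Ct, mg/L).
tc_remaining <- function(tc) {
  if (tc_kind(tc) == "remaining") tc$value else tc_ci(tc) - tc$value
}

#' Read / write time-course CSV
#'
#' Dialect: header `ci_mg_per_L,time_h,replicate,ct_mg_per_L` (remaining
#' concentrations), or `od` in place of `ct_mg_per_L`, in which case the
#' readings are routed through a calibration curve.
#'
#' @param path File path.
#' @param calibration Optional [fit_calibration()] curve, required when
#'   the file carries an `od` column.
#' @param ... Metadata passed on to [time_course()].
#' @return A `time_course` (the file must contain a single `ci_mg_per_L`).
#' @export
read_time_course_csv <- function(path, calibration = NULL, ...) {
  raw <- readr::read_csv(path, col_types = readr::cols())
  if (!"ct_mg_per_L" %in% names(raw)) {
    if (!"od" %in% names(raw)) {
      abort("Time-course CSV needs `ct_mg_per_L` or `od`.",
            class = "biosorb_invalid_input")
    }
    if (is.null(calibration)) {
      abort("`calibration` curve required to convert `od` readings.",
            class = "biosorb_invalid_input")
    }
    raw$ct_mg_per_L <- od_to_concentration(raw$od, calibration)
  }
  ci <- unique(raw$ci_mg_per_L)
  if (length(ci) != 1) {
    abort("File must contain exactly one initial concentration.",
          class = "biosorb_invalid_input")
  }
  time_course(
    tibble(time_h = raw$time_h, replicate = raw$replicate,
           value = raw$ct_mg_per_L),
    ci = ci, value_kind = "remaining", ...
  )
}

#' @rdname read_time_course_csv
#' @param tc A `time_course`.
#' @export
write_time_course_csv <- function(tc, path) {
  readr::write_csv(
    tibble(ci_mg_per_L = tc_ci(tc), time_h = tc$time_h,
           replicate = tc$replicate, ct_mg_per_L = tc_remaining(tc)),
    path
  )
  invisible(path)
}
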