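#' Plot a kinetic time course
#'
#' Observed points (one shape per replicate) over time, in the space the
#' course was recorded in.
#'
#' @param object A [time_course()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.time_course <- function(object, ...) {
  ylab <- if (tc_kind(object) == "adsorbed") "q (mg/g)" else "Ct (mg/L)"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                        alpha = 0.8) +
    ggplot2::labs(x = "time (h)", y = ylab, shape = "replicate",
                  title = paste0("Time course, Ci = ", tc_ci(object),
                                 " mg/L")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted kinetic curve
#'
#' Pooled observed adsorbed amounts with the fitted model curve overlaid.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, ...) {
  obs <- object$observed
  yvar <- if (object$model == "first_order") "q_obs" else "ct_obs"
  tmax <- max(obs$time_h)
  curve <- tibble(
    time_h = seq(0, tmax, length.out = 200),
    value = predict(object, seq(0, tmax, length.out = 200),
                    space = if (object$model == "first_order")
                      "adsorbed" else "remaining")
  )
  ggplot2::ggplot(obs, ggplot2::aes(.data$time_h, .data[[yvar]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$time_h, .data$value),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "time (h)",
      y = if (object$model == "first_order") "q (mg/g)" else "Ct (mg/L)",
      title = sprintf("%s fit, Ci = %s mg/L",
                      if (object$model == "first_order")
                        "Pseudo-first-order" else "Ho second-order",
                      object$ci)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an isotherm fit
#'
#' Equilibrium points with the through-origin line.
#'
#' @param object An `isotherm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.isotherm_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$ce_mg_per_L, .data$qe_mg_per_g)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "steelblue") +
    ggplot2::labs(x = "Ce (mg/L)", y = "qe (mg/g)",
                  title = sprintf("C-type isotherm%s: b_o = %.3f L/g",
                                  if (is.na(object$temperature_C)) "" else
                                    sprintf(" (%g degC)", object$temperature_C),
                                  object$slope)) +
    ggplot2::theme_minimal()
}

#' Plot a pH screen
#'
#' Replicate removal percentages against pH with the replicate mean.
#'
#' @param data A tibble from [generate_ph_screen()] (columns `ph`,
#'   `removal_percent`).
#' @return A ggplot.
#' @export
plot_ph_screen <- function(data) {
  means <- data |>
    dplyr::group_by(.data$ph) |>
    dplyr::summarise(removal_percent = mean(.data$removal_percent),
                     .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(.data$ph, .data$removal_percent)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = means, colour = "steelblue") +
    ggplot2::labs(x = "pH", y = "removal (%)") +
    ggplot2::theme_minimal()
}
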