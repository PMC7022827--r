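#' Model selection criterion (MSC)
#'
#' The MSC scores a fitted model against observations as the log ratio of
#' the weighted total sum of squares (about the observed mean) to the
#' weighted residual sum of squares, penalised by the parameter count:
#' `MSC = ln(sum w (C - Cbar)^2 / sum w (C - Cm)^2) - 2 * lambda / d`,
#' with `d` observations and `lambda` fitted parameters. Larger is
#' better. The ratio is invariant to a uniform rescaling of the weights.
#'
#' A perfect fit (zero residual sum of squares) raises a typed error —
#' the criterion would be infinite and reports should never hold
#' non-finite numbers silently. A constant observed series has zero
#' numerator and returns `-Inf` with a warning.
#'
#' @param observed,modeled Equal-length numeric vectors (length >= 2).
#' @param n_params Number of fitted parameters, `lambda` (>= 1).
#' @param weights Optional positive per-point weights; default uniform.
#' @return A single number (dimensionless).
#' @examples
#' msc(c(10, 20, 30), c(11, 19, 31), n_params = 1)  # log(200/3) - 2/3
#' @export
msc <- function(observed, modeled, n_params = 1, weights = NULL) {
  d <- length(observed)
  if (d < 2 || length(modeled) != d) {
    abort("`observed` and `modeled` must be equal length >= 2.",
          class = "biosorb_invalid_input")
  }
  w <- weights %||% rep(1, d)
  if (length(w) != d || any(w <= 0)) {
    abort("`weights` must be positive and match the data length.",
          class = "biosorb_invalid_input")
  }
  cbar <- sum(w * observed) / sum(w)
  tss <- sum(w * (observed - cbar)^2)
  rss <- sum(w * (observed - modeled)^2)
  if (rss == 0) {
    abort("Perfect fit: residual sum of squares is zero, MSC undefined.",
          class = "biosorb_perfect_fit")
  }
  if (tss == 0) {
    warn("Constant observed series: MSC is -Inf.",
         class = "biosorb_constant_series")
    return(-Inf)
  }
  log(tss / rss) - 2 * n_params / d
}

#' Residual error summaries
#'
#' `rmse()` is `sqrt(RSS / d)`; `rse()` is the residual standard error
#' `sqrt(RSS / (d - lambda))`, which divides by the residual degrees of
#' freedom and therefore always satisfies `rse >= rmse`. Nonlinear fits
#' are summarised by these instead of an R-squared.
#'
#' @inheritParams msc
#' @return A single number in the units of the observations.
#' @export
rmse <- function(observed, modeled) {
  if (length(observed) != length(modeled)) {
    abort("Length mismatch.", class = "biosorb_invalid_input")
  }
  sqrt(sum((observed - modeled)^2) / length(observed))
}

#' @rdname rmse
#' @export
rse <- function(observed, modeled, n_params = 1) {
  d <- length(observed)
  if (d != length(modeled)) {
    abort("Length mismatch.", class = "biosorb_invalid_input")
  }
  if (d <= n_params) {
    abort("Need more observations than parameters for RSE.",
          class = "biosorb_degenerate_input")
  }
  sqrt(sum((observed - modeled)^2) / (d - n_params))
}

#' Compare the two kinetic models on one time course
#'
#' Scores the first-order and second-order fits of the same time course
#' side by side: MSC, RMSE and RSE per model, and the preferred model
#' (strictly greater MSC; exact ties are flagged). Both models are scored
#' on the same observed series — the pooled replicate adsorbed amounts,
#' the space the fits themselves target (second-order predictions are
#' mapped through the mass balance `q = Ci - Ct`). Each model has one
#' fitted parameter.
#'
#' @param tc The [time_course()] both models were fitted to.
#' @param first_order A `first_order_fit` for `tc`.
#' @param second_order A `second_order_fit` for `tc`.
#' @param weights Optional per-point MSC weights; default uniform.
#' @return A `model_comparison`: tibble with one row per model (columns
#'   `model`, `rate_constant`, `rate_constant_se`, `msc`, `rmse`, `rse`,
#'   `n_obs`, `n_params`) and attributes `preferred_model` and `tie`.
#' @export
compare_kinetic_models <- function(tc, first_order, second_order,
                                   weights = NULL) {
  stopifnot(inherits(first_order, "first_order_fit"),
            inherits(second_order, "second_order_fit"))
  if (!identical(first_order$ci, tc_ci(tc)) ||
      !identical(second_order$ci, tc_ci(tc))) {
    abort("Fits and time course disagree on the initial concentration.",
          class = "biosorb_invalid_input")
  }
  q_obs <- tc_adsorbed(tc)
  t_obs <- tc$time_h
  q_fo <- predict(first_order, t_obs, space = "adsorbed")
  q_so <- predict(second_order, t_obs, space = "adsorbed")

  row <- function(fit, q_mod) {
    tibble(
      model = fit$model,
      rate_constant = fit$rate_constant,
      rate_constant_se = fit$rate_constant_se,
      msc = msc(q_obs, q_mod, n_params = 1, weights = weights),
      rmse = rmse(q_obs, q_mod),
      rse = rse(q_obs, q_mod, n_params = 1),
      n_obs = length(q_obs),
      n_params = 1L
    )
  }
  out <- dplyr::bind_rows(row(first_order, q_fo), row(second_order, q_so))
  tie <- out$msc[1] == out$msc[2]
  if (tie) {
    warn("MSC tie between models.", class = "biosorb_msc_tie")
  }
  structure(out,
            class = c("model_comparison", class(out)),
            preferred_model = if (tie) NA_character_ else
              out$model[which.max(out$msc)],
            tie = tie)
}

#' @export
print.model_comparison <- function(x, ...) {
  NextMethod()
  cat("preferred model:", attr(x, "preferred_model"), "\n")
  invisible(x)
}

#' Preferred model of a comparison
#' @param comparison A `model_comparison` from [compare_kinetic_models()].
#' @return `"first_order"`, `"second_order"`, or `NA` on a tie.
#' @export
preferred_model <- function(comparison) attr(comparison, "preferred_model")
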