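#' Definitional adsorption quantities
#'
#' The three definitional quantities of a batch biosorption experiment:
#' removal percentage `D = 100 * (Ci - Ct) / Ci`, total adsorption
#' `Q = Ci - Ct` (mg/L), and adsorption capacity `q = Q / B` (mg per g of
#' biosorbent). With biomass fixed at 1 g/L — the study design used
#' throughout — `q` is numerically equal to `Q`.
#'
#' `Ct > Ci` (negative adsorption, possible under measurement noise) is
#' allowed and propagated with a warning rather than clipped.
#'
#' @param ci Initial concentration, mg/L (> 0).
#' @param ct Concentration at time t, mg/L.
#' @param q_total Total adsorption Q, mg/L.
#' @param biomass Biosorbent concentration B, g/L (> 0).
#' @return Numeric vector: percent for [removal_percent()], mg/L for
#'   [total_adsorption()], mg/g for [adsorption_capacity()].
#' @examples
#' removal_percent(25, 1.9)       # 92.4
#' total_adsorption(50, 4.6)      # 45.4
#' adsorption_capacity(45.4, 1)   # 45.4
#' @export
removal_percent <- function(ci, ct) {
  if (any(ci <= 0)) {
    abort("`ci` must be > 0.", class = "biosorb_invalid_input")
  }
  warn_if_supersaturated(ci, ct)
  100 * (ci - ct) / ci
}

#' @rdname removal_percent
#' @export
total_adsorption <- function(ci, ct) {
  if (any(ci <= 0)) {
    abort("`ci` must be > 0.", class = "biosorb_invalid_input")
  }
  warn_if_supersaturated(ci, ct)
  ci - ct
}

#' @rdname removal_percent
#' @export
adsorption_capacity <- function(q_total, biomass) {
  if (any(biomass <= 0)) {
    abort("`biomass` must be > 0.", class = "biosorb_invalid_input")
  }
  q_total / biomass
}

warn_if_supersaturated <- function(ci, ct) {
  if (any(ct > ci)) {
    warn("Ct exceeds Ci for some observations (negative adsorption); propagated unclipped.",
         class = "biosorb_negative_adsorption")
  }
}

#' Add adsorption quantities to a record table
#'
#' Convenience verb: given a table with columns `ci_mg_per_L`,
#' `ct_mg_per_L` and optionally `biomass_g_per_L` (default 1), appends
#' `removal_percent`, `q_mg_per_L` and `q_mg_per_g` columns. Percentages
#' printed in reports are rounded half-away-from-zero to 2 decimals; the
#' returned columns keep full precision.
#'
#' @param data A data frame of adsorption records.
#' @param biomass Fallback biomass (g/L) when the column is absent.
#' @return The input as a tibble with quantity columns appended.
#' @export
add_adsorption_quantities <- function(data, biomass = 1) {
  stopifnot(is.data.frame(data))
  b <- if ("biomass_g_per_L" %in% names(data)) data$biomass_g_per_L else biomass
  dplyr::mutate(
    as_tibble(data),
    removal_percent = removal_percent(.data$ci_mg_per_L, .data$ct_mg_per_L),
    q_mg_per_L = total_adsorption(.data$ci_mg_per_L, .data$ct_mg_per_L),
    q_mg_per_g = adsorption_capacity(.data$q_mg_per_L, b)
  )
}
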