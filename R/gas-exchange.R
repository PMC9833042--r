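#' Construct a gas-exchange A-Ci curve
#'
#' A curve is a tibble with one row per stabilised CO2 step (open-system
#' cuvette log) carrying columns `c_a`, `c_i` (umol mol-1), `a_net`
#' (umol CO2 m-2 s-1), `g_s` (mol H2O m-2 s-1), `t_leaf` (degC) and
#' `pressure` (kPa), plus per-plant metadata stored as attributes:
#' `plant_id`, `growth` (growth-temperature label), `measurement`
#' (measurement temperature, degC), `r_d` (dark respiration, measured, not
#' fitted) and `rubisco_sites` (umol m-2, optional).
#'
#' @param data Data frame with the six step columns.
#' @param plant_id Plant identifier.
#' @param growth Growth-treatment label.
#' @param measurement Measurement temperature, degC.
#' @param r_d Dark respiration, umol m-2 s-1 (>= 0).
#' @param rubisco_sites Rubisco catalytic-site content, umol m-2, or `NA`.
#' @return A `gas_exchange` tibble.
#' @export
gas_exchange_curve <- function(data, plant_id = "plant1", growth = "",
                               measurement = NA_real_, r_d = 0,
                               rubisco_sites = NA_real_) {
  curve <- as_tibble(data)
  attr(curve, "meta") <- list(
    plant_id = plant_id, growth = growth, measurement = measurement,
    r_d = r_d, rubisco_sites = rubisco_sites
  )
  class(curve) <- c("gas_exchange", class(curve))
  validate_gas_exchange(curve)
  curve
}

#' @rdname gas_exchange_curve
#' @param curve A `gas_exchange` tibble.
#' @export
curve_meta <- function(curve) {
  attr(curve, "meta") %||%
    list(plant_id = NA_character_, growth = "", measurement = NA_real_,
         r_d = NA_real_, rubisco_sites = NA_real_)
}

ge_columns <- c("c_a", "c_i", "a_net", "g_s", "t_leaf", "pressure")

#' Validate a gas-exchange curve
#'
#' Checks the column schema, that the curve has at least 6 CO2 steps, that
#' `c_i < c_a` wherever net assimilation is positive, and that the metadata
#' respiration is non-negative.
#'
#' @param curve A `gas_exchange` tibble (or plain data frame with the step
#'   columns).
#' @return `curve`, invisibly; errors describe the first violated rule.
#' @export
validate_gas_exchange <- function(curve) {
  missing <- setdiff(ge_columns, names(curve))
  if (length(missing)) {
    abort(sprintf("gas-exchange curve is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "rubiscotherm_schema_error")
  }
  for (col in ge_columns) {
    if (!is.numeric(curve[[col]])) {
      abort(sprintf("column '%s' must be numeric.", col),
            class = "rubiscotherm_schema_error")
    }
  }
  if (nrow(curve) < 6L) {
    abort("a gas-exchange curve needs >= 6 CO2 steps.", class = "rubiscotherm_input_error")
  }
  bad <- which(curve$a_net > 0 & curve$c_i >= curve$c_a)
  if (length(bad)) {
    abort(sprintf("c_i must be below c_a where a_net > 0 (row %d violates this).", bad[1]),
          class = "rubiscotherm_input_error")
  }
  meta <- curve_meta(curve)
  if (!is.na(meta$r_d) && meta$r_d < 0) {
    abort("metadata r_d must be non-negative.", class = "rubiscotherm_input_error")
  }
  invisible(curve)
}

#' Add the implied chloroplastic CO2 to a curve
#'
#' `c_c = c_i - a_net / g_m` using a (typically fitted) mesophyll
#' conductance.
#'
#' @param data Data frame with `c_i` and `a_net` columns.
#' @param g_m Mesophyll conductance, mol CO2 m-2 s-1 (> 0 or `Inf`).
#' @return `data` with a `c_c` column appended.
#' @export
add_chloroplastic_co2 <- function(data, g_m) {
  if (is.na(g_m) || g_m <= 0) {
    abort("`g_m` must be positive.", class = "rubiscotherm_domain_error")
  }
  dplyr::mutate(data, c_c = if (is.finite(g_m)) .data$c_i - .data$a_net / g_m else .data$c_i)
}
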