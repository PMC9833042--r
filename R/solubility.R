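#' Henry's-law solubility table for CO2 and O2
#'
#' Temperature-indexed Henry coefficients (uM dissolved per ubar partial
#' pressure) used to bridge dissolved-phase Rubisco kinetics (uM) and
#' gas-phase cuvette concentrations (umol mol-1). The bundled default covers
#' 0-40 degC in 5 degC steps; CO2 coefficients follow Carroll, Slupsky &
#' Mather (1991, J. Phys. Chem. Ref. Data) and O2 coefficients Benson &
#' Krause (1984, Limnol. Oceanogr.), both for pure water.
#'
#' @param path Optional path to a replacement table (TSV with columns
#'   `temperature`, `co2`, `o2`). The default loads the bundled table.
#' @return Tibble with columns `temperature` (degC), `co2`, `o2`
#'   (uM ubar-1), validated for positivity and monotone decline with
#'   temperature.
#' @examples
#' gas_solubility()
#' @export
gas_solubility <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gas_solubility.tsv", package = "rubiscotherm")
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("temperature", "co2", "o2")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(sprintf("solubility table is missing column(s): %s", paste(missing, collapse = ", ")),
          class = "rubiscotherm_schema_error")
  }
  tbl <- dplyr::arrange(tbl, .data$temperature)
  if (any(tbl$co2 <= 0) || any(tbl$o2 <= 0)) {
    abort("solubility coefficients must be strictly positive.", class = "rubiscotherm_input_error")
  }
  if (any(diff(tbl$co2) >= 0) || any(diff(tbl$o2) >= 0)) {
    abort("solubility must decrease monotonically with temperature.",
          class = "rubiscotherm_input_error")
  }
  tbl
}

henry_coefficient <- function(t, gas = c("CO2", "O2"), sol = gas_solubility()) {
  gas <- match.arg(gas)
  rng <- range(sol$temperature)
  if (any(t < rng[1] | t > rng[2])) {
    abort(sprintf("temperature outside the solubility table range [%g, %g] degC.",
                  rng[1], rng[2]),
          class = "rubiscotherm_domain_error")
  }
  col <- if (gas == "CO2") sol$co2 else sol$o2
  approx(sol$temperature, col, t)$y
}

#' Dissolved concentration of CO2 or O2 at equilibrium
#'
#' Converts a gas-phase mole fraction to a dissolved concentration via the
#' gas's partial pressure and a linearly interpolated Henry coefficient.
#'
#' @param mole_fraction Gas-phase mole fraction, umol mol-1 (ppm).
#' @param pressure Total air pressure, kPa.
#' @param t Temperature, degC (within the solubility table range).
#' @param gas `"CO2"` or `"O2"`.
#' @param sol Solubility table, see [gas_solubility()].
#' @return Dissolved concentration, uM.
#' @examples
#' dissolved_concentration(210000, 101.325, 25, "O2") # ~ 265 uM
#' @export
dissolved_concentration <- function(mole_fraction, pressure, t, gas = c("CO2", "O2"),
                                    sol = gas_solubility()) {
  gas <- match.arg(gas)
  if (any(pressure <= 0)) {
    abort("`pressure` must be positive.", class = "rubiscotherm_domain_error")
  }
  if (any(mole_fraction < 0)) {
    abort("`mole_fraction` must be non-negative.", class = "rubiscotherm_domain_error")
  }
  ## partial pressure in ubar: ppm * (kPa -> bar) ; 1 bar = 1e6 ubar
  p_ubar <- mole_fraction * pressure / 100
  p_ubar * henry_coefficient(t, gas, sol)
}

#' Gas-phase mole fraction equivalent of a dissolved concentration
#'
#' Inverse of [dissolved_concentration()].
#'
#' @param concentration Dissolved concentration, uM.
#' @inheritParams dissolved_concentration
#' @return Mole fraction, umol mol-1.
#' @export
gas_mole_fraction <- function(concentration, pressure, t, gas = c("CO2", "O2"),
                              sol = gas_solubility()) {
  gas <- match.arg(gas)
  if (any(pressure <= 0)) {
    abort("`pressure` must be positive.", class = "rubiscotherm_domain_error")
  }
  concentration / henry_coefficient(t, gas, sol) / (pressure / 100)
}
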