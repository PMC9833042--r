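#' Temperature response of a kinetic parameter
#'
#' Bundles a Rubisco kinetic constant measured at 25 degC with the activation
#' energy of its exponential temperature response, plus optional standard
#' errors. The response is evaluated with [arrhenius_value()]:
#' \deqn{P(T) = P(25) \exp\left[\frac{(T-25)\,E_a}{298\,R\,(273+T)}\right]}
#' with \eqn{T} in degC, \eqn{E_a} in kJ mol-1 (converted internally to
#' J mol-1) and \eqn{R} = 8.314 J K-1 mol-1.
#'
#' @param value_25 Parameter value at 25 degC (units of the parameter; > 0).
#' @param e_a Activation energy, kJ mol-1. May be negative: the CO2/O2
#'   specificity factor declines with temperature (apparent Ea around -20 to
#'   -24 kJ mol-1).
#' @param se_25,se_ea Optional non-negative standard errors.
#' @return An object of class `temperature_response`.
#' @seealso [arrhenius_value()], [fit_arrhenius()]
#' @examples
#' kc <- temperature_response(11.8, 54.8)
#' arrhenius_value(kc, 35)
#' @export
temperature_response <- function(value_25, e_a, se_25 = NA_real_, se_ea = NA_real_) {
  stopifnot(is.numeric(value_25), length(value_25) == 1L,
            is.numeric(e_a), length(e_a) == 1L)
  if (!is.finite(value_25) || value_25 <= 0) {
    abort("`value_25` must be a finite positive number.", class = "rubiscotherm_input_error")
  }
  if (!is.na(se_25) && se_25 < 0 || !is.na(se_ea) && se_ea < 0) {
    abort("standard errors must be non-negative.", class = "rubiscotherm_input_error")
  }
  structure(
    list(value_25 = value_25, e_a = e_a, se_25 = se_25, se_ea = se_ea),
    class = "temperature_response"
  )
}

#' @export
print.temperature_response <- function(x, ...) {
  cat(sprintf("<temperature_response> value(25 degC) = %g", x$value_25))
  if (!is.na(x$se_25)) cat(sprintf(" (SE %g)", x$se_25))
  cat(sprintf(", Ea = %g kJ/mol", x$e_a))
  if (!is.na(x$se_ea)) cat(sprintf(" (SE %g)", x$se_ea))
  cat("\n")
  invisible(x)
}

## bare-metal Arrhenius kernel, vectorised over t (degC), ea in kJ/mol
arrhenius_kernel <- function(value_25, e_a, t) {
  value_25 * exp((t - 25) * e_a * 1000 / (298 * R_GAS * (273 + t)))
}

check_temperature <- function(t, range = c(-10, 60)) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("temperature must be finite numeric.", class = "rubiscotherm_domain_error")
  }
  if (any(t < range[1] | t > range[2])) {
    abort(
      sprintf("temperature outside the physical range [%g, %g] degC.", range[1], range[2]),
      class = "rubiscotherm_domain_error"
    )
  }
  invisible(t)
}

#' Evaluate a temperature response at a given leaf/assay temperature
#'
#' @param tr A [temperature_response()].
#' @param t Temperature(s), degC, in -10..60.
#' @return Parameter value(s) at `t`, same units as `tr$value_25`.
#' @examples
#' arrhenius_value(temperature_response(3.31, 54.2), 25) # exactly 3.31
#' @export
arrhenius_value <- function(tr, t) {
  stopifnot(inherits(tr, "temperature_response"))
  check_temperature(t)
  arrhenius_kernel(tr$value_25, tr$e_a, t)
}

#' Fit an Arrhenius temperature response to assay data
#'
#' Nonlinear least squares of the exponential temperature-response form on the
#' original measurement scale. Starting values come from the exact
#' log-linearisation (the model is linear in `log(value_25)` and `e_a` after
#' taking logs), so convergence is essentially guaranteed for data that
#' resemble an exponential response.
#'
#' @param data Data frame with one row per assay measurement.
#' @param temperature,value Column names (tidy-eval) holding assay temperature
#'   (degC) and the measured parameter value (> 0). Defaults `temperature`,
#'   `value`.
#' @return An `arrhenius_fit` object; `$tr` is the fitted
#'   [temperature_response()] with standard errors, `$data` carries fitted
#'   values and residuals. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(temperature = c(10, 15, 20, 25, 30, 35),
#'                     value = arrhenius_value(temperature_response(2.78, 48.7), temperature))
#' fit_arrhenius(d)$tr
#' @export
fit_arrhenius <- function(data, temperature = temperature, value = value) {
  temps <- dplyr::pull(data, {{ temperature }})
  vals <- dplyr::pull(data, {{ value }})
  if (length(unique(temps)) < 3L) {
    abort("need measurements at >= 3 distinct temperatures.", class = "rubiscotherm_input_error")
  }
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all parameter values must be finite and positive.", class = "rubiscotherm_input_error")
  }
  check_temperature(temps)

  ## exact linearisation: log v = log v25 + x * ea  with x = (t-25)*1000/(298 R (273+t))
  x <- (temps - 25) * 1000 / (298 * R_GAS * (273 + temps))
  lin <- lm(log(vals) ~ x)
  start <- list(v25 = exp(coef(lin)[[1]]), ea = coef(lin)[[2]])

  df <- data.frame(t = temps, v = vals)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ v25 * exp((t - 25) * ea * 1000 / (298 * 8.314 * (273 + t))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      abort(
        paste0("Arrhenius fit did not converge: ", conditionMessage(e),
               sprintf(" [start v25=%.4g, ea=%.4g, n=%d]", start$v25, start$ea, length(vals))),
        class = "rubiscotherm_fit_error"
      )
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(v25 = NA_real_, ea = NA_real_))
  structure(
    list(
      tr = temperature_response(est[["v25"]], est[["ea"]], se[["v25"]], se[["ea"]]),
      fit = fit,
      data = tibble(
        temperature = temps, value = vals,
        fitted = stats::fitted(fit), residual = stats::residuals(fit)
      )
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Arrhenius temperature-response fit\n")
  print(x$tr)
  cat(sprintf("  n = %d, RMSE = %g\n", nrow(x$data), sqrt(mean(x$data$residual^2))))
  invisible(x)
}

#' @rdname fit_arrhenius
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(
    term = c("value_25", "e_a"),
    estimate = c(x$tr$value_25, x$tr$e_a),
    std.error = c(x$tr$se_25, x$tr$se_ea)
  )
}

#' @rdname fit_arrhenius
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(
    nobs = nrow(x$data),
    rmse = sqrt(mean(x$data$residual^2)),
    sigma = tryCatch(summary(x$fit)$sigma, error = function(e) NA_real_)
  )
}

#' A set of Rubisco kinetic constants with temperature responses
#'
#' Houses the four constants that characterise Rubisco catalysis: the
#' carboxylation turnover rate kcatCO2 (s-1), the CO2/O2 specificity factor
#' SC/O (M M-1), and the Michaelis constants for CO2 (KC, uM dissolved) and
#' O2 (KO, uM dissolved), each as a [temperature_response()].
#'
#' @param kcat_co2,s_co,k_c,k_o [temperature_response()] objects.
#' @param label Growth-treatment tag, e.g. `"10C"`.
#' @return An object of class `rubisco_kinetics`.
#' @examples
#' k <- arabidopsis_kinetics("10C")
#' kinetics_at_temperature(k, 35)
#' @export
rubisco_kinetics <- function(kcat_co2, s_co, k_c, k_o, label = "") {
  for (tr in list(kcat_co2, s_co, k_c, k_o)) {
    stopifnot(inherits(tr, "temperature_response"))
  }
  if (k_o$value_25 <= k_c$value_25) {
    abort("KO(25) must exceed KC(25).", class = "rubiscotherm_input_error")
  }
  structure(
    list(kcat_co2 = kcat_co2, s_co = s_co, k_c = k_c, k_o = k_o, label = label),
    class = "rubisco_kinetics"
  )
}

#' @export
print.rubisco_kinetics <- function(x, ...) {
  cat(sprintf("<rubisco_kinetics> label: %s\n", x$label))
  cat(sprintf("  kcatCO2: %g s-1 (Ea %g)\n", x$kcat_co2$value_25, x$kcat_co2$e_a))
  cat(sprintf("  SC/O:    %g M M-1 (Ea %g)\n", x$s_co$value_25, x$s_co$e_a))
  cat(sprintf("  KC:      %g uM (Ea %g)\n", x$k_c$value_25, x$k_c$e_a))
  cat(sprintf("  KO:      %g uM (Ea %g)\n", x$k_o$value_25, x$k_o$e_a))
  invisible(x)
}

#' Evaluate all four kinetic constants at a temperature
#'
#' @param k A [rubisco_kinetics()] object.
#' @param t Temperature, degC.
#' @return One-row tibble with `label`, `temperature`, `kcat_co2`, `s_co`,
#'   `k_c`, `k_o` (uM for the Michaelis constants).
#' @export
kinetics_at_temperature <- function(k, t) {
  stopifnot(inherits(k, "rubisco_kinetics"))
  check_temperature(t)
  tibble(
    label = k$label,
    temperature = t,
    kcat_co2 = arrhenius_value(k$kcat_co2, t),
    s_co = arrhenius_value(k$s_co, t),
    k_c = arrhenius_value(k$k_c, t),
    k_o = arrhenius_value(k$k_o, t)
  )
}

#' Apparent Michaelis constant for CO2 in the presence of O2
#'
#' Competitive-inhibition form `KC (1 + O / KO)`; all three arguments in the
#' same dissolved-concentration units (uM).
#'
#' @param k_c Michaelis constant for CO2, uM.
#' @param k_o Michaelis constant for O2, uM (> 0).
#' @param o Dissolved O2 concentration, uM (>= 0).
#' @return Apparent KC at the given O2, uM (>= `k_c`).
#' @examples
#' kc_apparent_o2(11.8, 275.6, 253)
#' @export
kc_apparent_o2 <- function(k_c, k_o, o) {
  if (any(k_c < 0) || any(o < 0)) {
    abort("`k_c` and `o` must be non-negative.", class = "rubiscotherm_domain_error")
  }
  if (any(k_o <= 0)) {
    abort("`k_o` must be strictly positive.", class = "rubiscotherm_domain_error")
  }
  k_c * (1 + o / k_o)
}

#' CO2 compensation point from the specificity factor
#'
#' `Gamma* = 0.5 O / SC/O`: at Gamma*, carboxylation exactly balances the CO2
#' released by photorespiration (half an oxygenation each). Dissolved units
#' in, dissolved units out; convert with [gas_mole_fraction()] for use in the
#' gas-phase assimilation model.
#'
#' @param s_co Specificity factor, M M-1 (> 0).
#' @param o Dissolved O2, uM (>= 0).
#' @return Gamma*, uM.
#' @examples
#' gamma_star_from_sco(78, 253)
#' @export
gamma_star_from_sco <- function(s_co, o) {
  if (any(s_co <= 0)) {
    abort("`s_co` must be strictly positive.", class = "rubiscotherm_domain_error")
  }
  if (any(o < 0)) {
    abort("`o` must be non-negative.", class = "rubiscotherm_domain_error")
  }
  0.5 * o / s_co
}
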