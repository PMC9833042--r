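#' Plot an A-Ci split fit
#'
#' Observed net assimilation against intercellular CO2, the fitted forward
#' model curve, limb assignment by colour and the chosen transition point.
#'
#' @param object An `aci_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aci_fit <- function(object, ...) {
  grid <- tibble(c_i = seq(min(object$data$c_i), max(object$data$c_i), length.out = 200))
  pred <- assimilation_ci(object$params, grid$c_i)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$c_i, y = .data$a_net)) +
    ggplot2::geom_line(
      data = pred,
      ggplot2::aes(x = .data$c_i, y = .data$a_net),
      colour = "grey40", inherit.aes = FALSE
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$limitation), size = 2) +
    ggplot2::geom_vline(xintercept = object$transition_ci, linetype = "dashed") +
    ggplot2::labs(
      x = expression(C[i] ~ (mu * mol ~ mol^-1)),
      y = expression(A[N] ~ (mu * mol ~ m^-2 ~ s^-1)),
      colour = "limitation",
      title = sprintf("Vcmax %.3g, Jmax %.3g, gm %.3g",
                      object$params$v_cmax, object$params$j_max, object$params$g_m)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an Arrhenius temperature-response fit
#'
#' @param object An `arrhenius_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  rng <- range(object$data$temperature)
  grid <- tibble(temperature = seq(rng[1], rng[2], length.out = 200))
  grid$value <- arrhenius_value(object$tr, grid$temperature)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$temperature, y = .data$value)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "temperature (°C)", y = "parameter value",
      title = sprintf("value(25) = %.4g, Ea = %.4g kJ/mol",
                      object$tr$value_25, object$tr$e_a)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten A-Cc fit
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_fit <- function(object, ...) {
  rng <- range(object$data$c_c)
  grid <- tibble(c_c = seq(rng[1], rng[2], length.out = 200))
  grid$a_gross <- object$vmax_term * (grid$c_c - object$gamma_star) /
    (grid$c_c + object$kc21_apparent)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$c_c, y = .data$a_gross)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(C[c] ~ (mu * mol ~ mol^-1)),
      y = expression(A[N] + R[d] ~ (mu * mol ~ m^-2 ~ s^-1)),
      title = sprintf("KC21%%O2 = %.4g, Vmax term = %.4g",
                      object$kc21_apparent, object$vmax_term)
    ) +
    ggplot2::theme_minimal()
}

#' Compare modelled carboxylation CO2 responses across treatments
#'
#' Draws equal-enzyme Michaelis-Menten carboxylation curves
#' ([vc_response()], kcatCO2 standing in for Vcmax) for each supplied
#' kinetics set at a measurement temperature, with the apparent Michaelis
#' constant evaluated at the ambient O2.
#'
#' @param kinetics_list Named list of [rubisco_kinetics()] objects.
#' @param t Measurement temperature, degC.
#' @param o2 Ambient O2 mole fraction, umol mol-1.
#' @param pressure Air pressure, kPa.
#' @param c_max Upper end of the dissolved CO2 axis, uM.
#' @param sol Solubility table.
#' @return A ggplot object.
#' @export
plot_vc_comparison <- function(kinetics_list, t, o2 = 210000, pressure = 101.325,
                               c_max = 40, sol = gas_solubility()) {
  o_um <- dissolved_concentration(o2, pressure, t, "O2", sol)
  curves <- purrr::imap_dfr(kinetics_list, function(kin, label) {
    kt <- kinetics_at_temperature(kin, t)
    kc21 <- kc_apparent_o2(kt$k_c, kt$k_o, o_um)
    tibble(
      label = label,
      c = seq(0, c_max, length.out = 200),
      vc = vc_response(kt$kcat_co2, seq(0, c_max, length.out = 200), kc21)
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$c, y = .data$vc,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(CO[2] ~ (mu * M)),
      y = expression(V[c] ~ (s^-1 ~ per ~ site)),
      colour = "growth", title = sprintf("modelled carboxylation at %g °C", t)
    ) +
    ggplot2::theme_minimal()
}
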