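## One FvCB limb fitted to (c_i, a_net) by least squares on the quadratic
## solution, parameters on log scale for positivity. `v` is Vcmax for the
## Rubisco limb and Jmax/4 for the RuBP-regeneration limb (with k = 2 Gamma*).
fit_one_limb <- function(c_i, a_net, k, gamma_star, r_d, v_start, gm_start) {
  objective <- function(par) {
    pred <- tryCatch(
      limb_quadratic_ci(c_i, exp(par[1]), k, gamma_star, r_d, exp(par[2])),
      error = function(e) NULL
    )
    if (is.null(pred) || any(!is.finite(pred))) return(1e10)
    sum((a_net - pred)^2)
  }
  start <- c(log(v_start), log(gm_start))
  fit <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  fit <- optim(fit$par, objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  list(v = exp(fit$par[1]), g_m = exp(fit$par[2]), ssr = fit$value,
       converged = fit$convergence == 0)
}

## Deterministic starting rate: linear LS of a_net + r_d on the infinite-gm
## saturation shape, floored away from zero.
start_rate <- function(c_i, a_net, k, gamma_star, r_d) {
  f <- (c_i - gamma_star) / (c_i + k)
  max(sum(f * (a_net + r_d)) / sum(f^2), 1)
}

#' Estimate gm, Vcmax and Jmax from an A-Ci curve (two-limb split fit)
#'
#' Implements the finite-mesophyll-conductance curve-fitting approach of
#' Ethier & Livingston: each FvCB limb becomes a quadratic in net
#' assimilation once `Cc = Ci - A/gm` is substituted, and (`Vcmax`, `gm`) are
#' fitted on the low-Ci (Rubisco-limited) segment while (`Jmax`, `gm`) are
#' fitted on the high-Ci (RuBP-regeneration-limited) segment. The transition
#' point is chosen among the observed Ci split positions (leaving at least 3
#' steps per limb) as the Ci that minimises the difference between the two
#' limb-wise gm estimates; the reported `g_m` is the mean of the two limb
#' estimates at the chosen split, and both are retained.
#'
#' Gamma* and the effective Michaelis constant are evaluated from in vitro
#' kinetics at the curve's mean leaf temperature and converted to gas-phase
#' units through the solubility bridge. Day respiration is a measured input,
#' never fitted.
#'
#' @param curve A [gas_exchange_curve()] (or data frame with the step
#'   columns).
#' @param kinetics A [rubisco_kinetics()] object for the plant's growth
#'   treatment.
#' @param o2 Ambient O2 mole fraction, umol mol-1.
#' @param r_d Day respiration, umol m-2 s-1; defaults to the curve metadata.
#' @param sol Solubility table ([gas_solubility()]).
#' @param gm_start Starting mesophyll conductance for the limb fits,
#'   mol m-2 s-1.
#' @param min_points_per_limb Minimum number of CO2 steps per limb (>= 3).
#' @return An `aci_fit` object with elements `params`
#'   ([fvcb_parameters()] with the fitted `v_cmax`, `j_max`, `g_m`),
#'   `transition_ci`, `gm_rubisco`, `gm_rubp`, `criterion`
#'   (`|gm_rubisco - gm_rubp|`), `rmse`, `n_points_per_limb`, `splits`
#'   (per-candidate diagnostics) and `data` (steps with fitted values,
#'   residuals, implied `c_c` and limb assignment). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' truth <- synthetic_truth(seed = 1, noise_sd_gas = 0)
#' curve <- generate_aci_curve(truth, "30C", 30)
#' fit <- fit_aci(curve, arabidopsis_kinetics("30C"))
#' tidy(fit)
#' @export
fit_aci <- function(curve, kinetics, o2 = 210000, r_d = NULL,
                    sol = gas_solubility(), gm_start = 0.15,
                    min_points_per_limb = 3L) {
  validate_gas_exchange(curve)
  stopifnot(inherits(kinetics, "rubisco_kinetics"))
  meta <- curve_meta(curve)
  r_d <- r_d %||% meta$r_d
  if (is.null(r_d) || is.na(r_d) || r_d < 0) {
    abort("`r_d` must be supplied (measured dark respiration, >= 0).",
          class = "rubiscotherm_input_error")
  }
  min_points_per_limb <- max(3L, as.integer(min_points_per_limb))

  t_leaf <- mean(curve$t_leaf)
  pressure <- mean(curve$pressure)
  kt <- kinetics_at_temperature(kinetics, t_leaf)
  o_um <- dissolved_concentration(o2, pressure, t_leaf, "O2", sol)
  k_m <- gas_mole_fraction(kc_apparent_o2(kt$k_c, kt$k_o, o_um), pressure, t_leaf, "CO2", sol)
  gamma_star <- gas_mole_fraction(gamma_star_from_sco(kt$s_co, o_um), pressure, t_leaf, "CO2", sol)

  ord <- order(curve$c_i)
  c_i <- curve$c_i[ord]
  a_net <- curve$a_net[ord]
  n <- length(c_i)
  if (n < 2L * min_points_per_limb) {
    abort(sprintf("need >= %d usable CO2 steps for the split fit (got %d).",
                  2L * min_points_per_limb, n),
          class = "rubiscotherm_input_error")
  }

  splits <- purrr::map(seq(min_points_per_limb, n - min_points_per_limb), function(j) {
    lo <- seq_len(j)
    hi <- seq(j + 1L, n)
    low <- fit_one_limb(c_i[lo], a_net[lo], k_m, gamma_star, r_d,
                        v_start = start_rate(c_i[lo], a_net[lo], k_m, gamma_star, r_d),
                        gm_start = gm_start)
    high <- fit_one_limb(c_i[hi], a_net[hi], 2 * gamma_star, gamma_star, r_d,
                         v_start = start_rate(c_i[hi], a_net[hi], 2 * gamma_star, gamma_star, r_d),
                         gm_start = gm_start)
    tibble(
      split = j, transition_ci = c_i[j],
      v_cmax = low$v, gm_rubisco = low$g_m, ssr_rubisco = low$ssr,
      j_max = 4 * high$v, gm_rubp = high$g_m, ssr_rubp = high$ssr,
      criterion = abs(low$g_m - high$g_m),
      converged = low$converged && high$converged
    )
  })
  splits <- dplyr::bind_rows(splits)
  usable <- dplyr::filter(splits, .data$converged, is.finite(.data$criterion))
  if (nrow(usable) == 0L) {
    abort(paste0("no candidate transition converged; per-split diagnostics:\n",
                 paste(utils::capture.output(print(splits)), collapse = "\n")),
          class = "rubiscotherm_fit_error")
  }
  best <- usable[which.min(usable$criterion), ]

  params <- fvcb_parameters(
    v_cmax = best$v_cmax, j_max = best$j_max, r_d = r_d,
    g_m = (best$gm_rubisco + best$gm_rubp) / 2,
    gamma_star = gamma_star, k_m = k_m
  )
  pred <- assimilation_ci(params, c_i)
  structure(
    list(
      params = params,
      transition_ci = best$transition_ci,
      gm_rubisco = best$gm_rubisco,
      gm_rubp = best$gm_rubp,
      criterion = best$criterion,
      rmse = sqrt(mean((a_net - pred$a_net)^2)),
      n_points_per_limb = c(rubisco = best$split, rubp = n - best$split),
      splits = splits,
      data = tibble(
        c_i = c_i, a_net = a_net,
        fitted = pred$a_net, residual = a_net - pred$a_net,
        c_c = pred$c_c, limitation = pred$limitation
      ),
      meta = meta,
      inputs = list(t_leaf = t_leaf, pressure = pressure, o2 = o2, r_d = r_d,
                    kinetics_label = kinetics$label)
    ),
    class = "aci_fit"
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("A-Ci split fit (finite mesophyll conductance)\n")
  cat(sprintf("  Vcmax = %.3g, Jmax = %.3g umol m-2 s-1, gm = %.3g mol m-2 s-1\n",
              x$params$v_cmax, x$params$j_max, x$params$g_m))
  cat(sprintf("  limb gm: rubisco %.3g / rubp %.3g (criterion %.2g)\n",
              x$gm_rubisco, x$gm_rubp, x$criterion))
  cat(sprintf("  transition Ci = %.4g umol mol-1 (%d + %d steps), RMSE = %.3g\n",
              x$transition_ci, x$n_points_per_limb[1], x$n_points_per_limb[2], x$rmse))
  invisible(x)
}

#' @rdname fit_aci
#' @param x An `aci_fit`.
#' @param ... Unused.
#' @export
tidy.aci_fit <- function(x, ...) {
  tibble(
    term = c("v_cmax", "j_max", "g_m", "gm_rubisco", "gm_rubp",
             "gamma_star", "k_m", "r_d"),
    estimate = c(x$params$v_cmax, x$params$j_max, x$params$g_m,
                 x$gm_rubisco, x$gm_rubp,
                 x$params$gamma_star, x$params$k_m, x$params$r_d)
  )
}

#' @rdname fit_aci
#' @export
glance.aci_fit <- function(x, ...) {
  tibble(
    nobs = nrow(x$data),
    rmse = x$rmse,
    transition_ci = x$transition_ci,
    criterion = x$criterion,
    n_rubisco = unname(x$n_points_per_limb["rubisco"]),
    n_rubp = unname(x$n_points_per_limb["rubp"])
  )
}
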