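#' In vivo apparent KC from an A-Cc curve (Michaelis-Menten fit)
#'
#' Regresses gross assimilation (`a_net + r_d`) on chloroplastic CO2 with
#' the RuBP-saturated Michaelis-Menten form
#' `A_gross = Vmax (Cc - Gamma*) / (Cc + KC21%O2)` by nonlinear least
#' squares. With `normalise_by_sites = TRUE` the fitted rate term is also
#' divided by the Rubisco catalytic-site content, turning it into an in vivo
#' kcatCO2 estimate (s-1).
#'
#' @param data Data frame with columns `c_c` and `a_net` (chloroplastic CO2
#'   typically from [add_chloroplastic_co2()] with a fitted gm). All `c_c`
#'   must be positive and not all equal to `gamma_star`.
#' @param gamma_star CO2 compensation point, same units as `c_c`.
#' @param r_d Day respiration added to `a_net` before fitting (measured, not
#'   fitted).
#' @param rubisco_sites Catalytic-site content, umol m-2 (required when
#'   `normalise_by_sites = TRUE`).
#' @param normalise_by_sites Report the rate term per catalytic site?
#' @return An `mm_fit` object: `kc21_apparent`, `vmax_term`, their standard
#'   errors, `kcat_in_vivo` (NA unless normalised), `rmse`, `data` with
#'   fitted values. Supports [tidy()] and [glance()].
#' @examples
#' cc <- seq(40, 600, length.out = 12)
#' d <- tibble::tibble(c_c = cc, a_net = 108.1 * (cc - 35) / (cc + 54.9) - 3.6)
#' fit_mm_kc21(d, gamma_star = 35, r_d = 3.6)
#' @export
fit_mm_kc21 <- function(data, gamma_star, r_d = 0, rubisco_sites = NULL,
                        normalise_by_sites = FALSE) {
  if (!all(c("c_c", "a_net") %in% names(data))) {
    abort("`data` needs columns `c_c` and `a_net`.", class = "rubiscotherm_schema_error")
  }
  c_c <- data$c_c
  a_gross <- data$a_net + r_d
  if (any(!is.finite(c_c)) || any(c_c <= 0)) {
    abort("all `c_c` must be positive; infer them with a valid g_m first.",
          class = "rubiscotherm_input_error")
  }
  if (all(abs(c_c - gamma_star) < sqrt(.Machine$double.eps) * max(1, gamma_star))) {
    abort("degenerate curve: every c_c sits at the compensation point.",
          class = "rubiscotherm_fit_error")
  }
  if (normalise_by_sites && (is.null(rubisco_sites) || is.na(rubisco_sites) ||
                             rubisco_sites <= 0)) {
    abort("`rubisco_sites` (> 0) is required when `normalise_by_sites = TRUE`.",
          class = "rubiscotherm_input_error")
  }

  df <- data.frame(c_c = c_c, a_gross = a_gross)
  start <- list(vmax = max(max(a_gross), 1) * 1.5, kc = median(c_c))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a_gross ~ vmax * (c_c - gamma_star) / (c_c + kc),
      data = df, start = start, lower = c(vmax = 1e-8, kc = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) {
      abort(paste0("Michaelis-Menten fit did not converge: ", conditionMessage(e)),
            class = "rubiscotherm_fit_error")
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, kc = NA_real_))
  resid <- stats::residuals(fit)
  structure(
    list(
      kc21_apparent = est[["kc"]],
      vmax_term = est[["vmax"]],
      se_kc21 = se[["kc"]],
      se_vmax = se[["vmax"]],
      kcat_in_vivo = if (normalise_by_sites) est[["vmax"]] / rubisco_sites else NA_real_,
      gamma_star = gamma_star,
      r_d = r_d,
      rmse = sqrt(mean(resid^2)),
      fit = fit,
      data = tibble(c_c = c_c, a_gross = a_gross,
                    fitted = stats::fitted(fit), residual = resid)
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten A-Cc fit (RuBP-saturated limb)\n")
  cat(sprintf("  KC21%%O2 = %.4g (SE %.3g), Vmax term = %.4g (SE %.3g)\n",
              x$kc21_apparent, x$se_kc21, x$vmax_term, x$se_vmax))
  if (!is.na(x$kcat_in_vivo)) {
    cat(sprintf("  in vivo kcatCO2 = %.4g s-1\n", x$kcat_in_vivo))
  }
  cat(sprintf("  n = %d, RMSE = %.3g\n", nrow(x$data), x$rmse))
  invisible(x)
}

#' @rdname fit_mm_kc21
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("kc21_apparent", "vmax_term", "kcat_in_vivo"),
    estimate = c(x$kc21_apparent, x$vmax_term, x$kcat_in_vivo),
    std.error = c(x$se_kc21, x$se_vmax, NA_real_)
  )
}

#' @rdname fit_mm_kc21
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(nobs = nrow(x$data), rmse = x$rmse)
}

#' Initial slope of an A-Cc curve
#'
#' Ordinary least-squares slope of net assimilation against chloroplastic
#' CO2 over the low-CO2 points (`c_c <= c_c_max`), the in vivo proxy for
#' Rubisco carboxylation efficiency.
#'
#' @param data Data frame with columns `c_c` and `a_net`.
#' @param c_c_max Retain points with `c_c` at or below this threshold
#'   (same units as `c_c`).
#' @return One-row tibble: `slope`, `se`, `intercept`, `n`.
#' @export
initial_slope <- function(data, c_c_max) {
  if (!all(c("c_c", "a_net") %in% names(data))) {
    abort("`data` needs columns `c_c` and `a_net`.", class = "rubiscotherm_schema_error")
  }
  keep <- dplyr::filter(data, .data$c_c <= c_c_max)
  if (nrow(keep) < 3L) {
    abort(sprintf("need >= 3 points with c_c <= %g (got %d).", c_c_max, nrow(keep)),
          class = "rubiscotherm_input_error")
  }
  fit <- lm(a_net ~ c_c, data = keep)
  sm <- summary(fit)$coefficients
  tibble(
    slope = sm["c_c", "Estimate"],
    se = sm["c_c", "Std. Error"],
    intercept = sm["(Intercept)", "Estimate"],
    n = nrow(keep)
  )
}
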