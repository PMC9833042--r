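#' Parameter set for the FvCB assimilation model
#'
#' Gas-phase (umol mol-1) parameterisation of the Farquhar-von
#' Caemmerer-Berry model for one leaf: maximum carboxylation rate `v_cmax`
#' (umol CO2 m-2 s-1), maximum electron transport `j_max` (umol e- m-2 s-1),
#' day respiration `r_d` (umol CO2 m-2 s-1), mesophyll conductance `g_m`
#' (mol CO2 m-2 s-1; `Inf` means chloroplast CO2 equals intercellular CO2),
#' CO2 compensation point `gamma_star` and effective Michaelis constant
#' `k_m` = KC(1 + O/KO), both umol mol-1.
#'
#' @param v_cmax,j_max,r_d,g_m,gamma_star,k_m See description; all
#'   non-negative, `g_m` may be `Inf`.
#' @return An object of class `fvcb_parameters`.
#' @seealso [fvcb_from_kinetics()] to derive `gamma_star`/`k_m` from in vitro
#'   kinetics.
#' @export
fvcb_parameters <- function(v_cmax, j_max, r_d, g_m, gamma_star, k_m) {
  vals <- c(v_cmax = v_cmax, j_max = j_max, r_d = r_d,
            gamma_star = gamma_star, k_m = k_m)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all FvCB parameters except `g_m` must be finite and non-negative.",
          class = "rubiscotherm_input_error")
  }
  if (is.na(g_m) || g_m <= 0) {
    abort("`g_m` must be positive (use Inf for an infinite conductance).",
          class = "rubiscotherm_input_error")
  }
  structure(
    list(v_cmax = v_cmax, j_max = j_max, r_d = r_d, g_m = g_m,
         gamma_star = gamma_star, k_m = k_m),
    class = "fvcb_parameters"
  )
}

#' @export
print.fvcb_parameters <- function(x, ...) {
  cat(sprintf(
    "<fvcb_parameters> Vcmax=%g, Jmax=%g, Rd=%g, gm=%g, Gamma*=%g, Km=%g\n",
    x$v_cmax, x$j_max, x$r_d, x$g_m, x$gamma_star, x$k_m
  ))
  invisible(x)
}

#' Derive gas-phase Gamma* and Km from in vitro kinetics
#'
#' Evaluates a treatment's Rubisco kinetics at the leaf temperature, computes
#' the dissolved-phase apparent KC at the ambient O2 level and Gamma* from
#' the specificity factor, and converts both to gas-phase mole fractions via
#' the solubility bridge.
#'
#' @param kin A [rubisco_kinetics()] object.
#' @param t Leaf temperature, degC.
#' @param v_cmax,j_max,r_d,g_m Leaf-level FvCB parameters (see
#'   [fvcb_parameters()]).
#' @param o2 Ambient O2 mole fraction, umol mol-1 (default 21%).
#' @param pressure Air pressure, kPa.
#' @param sol Solubility table ([gas_solubility()]).
#' @return An [fvcb_parameters()] object.
#' @export
fvcb_from_kinetics <- function(kin, t, v_cmax, j_max, r_d, g_m,
                               o2 = 210000, pressure = 101.325,
                               sol = gas_solubility()) {
  kt <- kinetics_at_temperature(kin, t)
  o_um <- dissolved_concentration(o2, pressure, t, "O2", sol)
  km_um <- kc_apparent_o2(kt$k_c, kt$k_o, o_um)
  gs_um <- gamma_star_from_sco(kt$s_co, o_um)
  fvcb_parameters(
    v_cmax = v_cmax, j_max = j_max, r_d = r_d, g_m = g_m,
    gamma_star = gas_mole_fraction(gs_um, pressure, t, "CO2", sol),
    k_m = gas_mole_fraction(km_um, pressure, t, "CO2", sol)
  )
}

## Gross carboxylation capacities at chloroplastic CO2 (umol mol-1).
## Net assimilation A = (1 - Gamma*/Cc) W - Rd with W the lesser capacity;
## above Gamma* this equals min over the per-limb net rates, below Gamma* it
## keeps the Rubisco limb limiting (the factor is negative there).
w_rubisco <- function(p, c_c) p$v_cmax * c_c / (c_c + p$k_m)
w_rubp <- function(p, c_c) p$j_max * c_c / (4 * c_c + 8 * p$gamma_star)

#' Net assimilation at a given chloroplastic CO2
#'
#' Evaluates both limbs of the FvCB model at chloroplastic CO2 `c_c`:
#' Rubisco-limited `Ac = Vcmax (Cc - Gamma*) / (Cc + Km) - Rd` and
#' RuBP-regeneration-limited `Aj = Jmax (Cc - Gamma*) / (4 Cc + 8 Gamma*) - Rd`
#' (NADPH-basis denominator, J = Jmax at saturating light), and returns the
#' limb with the smaller gross carboxylation rate together with its
#' limitation tag. At `c_c = gamma_star` the net rate is exactly `-r_d`.
#'
#' @param params An [fvcb_parameters()] object.
#' @param c_c Chloroplastic CO2 mole fraction(s), umol mol-1 (>= 0).
#' @return Tibble with columns `c_c`, `a_net`, `limitation`
#'   (`"rubisco"` / `"rubp_regeneration"`).
#' @examples
#' p <- fvcb_parameters(100, 120, 2, Inf, 40, 600)
#' assimilation_cc(p, c(40, 300, 2000))
#' @export
assimilation_cc <- function(params, c_c) {
  stopifnot(inherits(params, "fvcb_parameters"))
  if (any(c_c < 0)) {
    abort("`c_c` must be non-negative.", class = "rubiscotherm_domain_error")
  }
  ## Wc <= Wj  <=>  Vcmax (4 Cc + 8 Gamma*) <= Jmax (Cc + Km); this form is
  ## continuous at Cc = 0 where both gross rates vanish.
  rubisco <- params$v_cmax * (4 * c_c + 8 * params$gamma_star) <=
    params$j_max * (c_c + params$k_m)
  a <- ifelse(
    rubisco,
    params$v_cmax * (c_c - params$gamma_star) / (c_c + params$k_m),
    params$j_max * (c_c - params$gamma_star) / (4 * c_c + 8 * params$gamma_star)
  ) - params$r_d
  tibble(
    c_c = c_c,
    a_net = a,
    limitation = ifelse(rubisco, "rubisco", "rubp_regeneration")
  )
}

## Physically admissible root of the limb quadratic obtained by substituting
## Cc = Ci - A/gm into A = v (Cc - gstar) / (Cc + k) - rd. The "+" root
## (with leading coefficient -1/gm) is the branch continuous with the
## infinite-gm solution.
limb_quadratic_ci <- function(c_i, v, k, gstar, r_d, g_m) {
  if (!is.finite(g_m)) {
    return(v * (c_i - gstar) / (c_i + k) - r_d)
  }
  qa <- -1 / g_m
  qb <- c_i + k + (v - r_d) / g_m
  qc <- r_d * (c_i + k) - v * (c_i - gstar)
  disc <- qb^2 - 4 * qa * qc
  if (any(disc < 0)) {
    abort("negative discriminant in the limb quadratic: inconsistent parameters.",
          class = "rubiscotherm_fit_error")
  }
  (-qb + sqrt(disc)) / (2 * qa)
}

#' Net assimilation at a given intercellular CO2 with finite mesophyll conductance
#'
#' Substitutes `Cc = Ci - A/gm` into each FvCB limb, solves the resulting
#' quadratic for the physically admissible root (the branch continuous with
#' the infinite-`gm` solution), and selects the limb with the smaller implied
#' gross carboxylation rate. With `g_m = Inf` this reduces exactly to
#' [assimilation_cc()] at `c_c = c_i`.
#'
#' @param params An [fvcb_parameters()] object.
#' @param c_i Intercellular CO2 mole fraction(s), umol mol-1 (>= 0).
#' @return Tibble with columns `c_i`, `c_c` (implied chloroplastic CO2),
#'   `a_net`, `limitation`.
#' @examples
#' p <- fvcb_parameters(108.1, 190.6, 3.6, 0.142, 60, 1000)
#' assimilation_ci(p, c(100, 300, 900))
#' @export
assimilation_ci <- function(params, c_i) {
  stopifnot(inherits(params, "fvcb_parameters"))
  if (any(c_i < 0)) {
    abort("`c_i` must be non-negative.", class = "rubiscotherm_domain_error")
  }
  a_r <- limb_quadratic_ci(c_i, params$v_cmax, params$k_m, params$gamma_star,
                           params$r_d, params$g_m)
  a_j <- limb_quadratic_ci(c_i, params$j_max / 4, 2 * params$gamma_star,
                           params$gamma_star, params$r_d, params$g_m)
  cc_r <- if (is.finite(params$g_m)) c_i - a_r / params$g_m else c_i
  cc_j <- if (is.finite(params$g_m)) c_i - a_j / params$g_m else c_i
  rubisco <- w_rubisco(params, pmax(cc_r, 0)) <= w_rubp(params, pmax(cc_j, 0))
  tibble(
    c_i = c_i,
    c_c = ifelse(rubisco, cc_r, cc_j),
    a_net = ifelse(rubisco, a_r, a_j),
    limitation = ifelse(rubisco, "rubisco", "rubp_regeneration")
  )
}

#' Michaelis-Menten CO2 response of Rubisco carboxylation
#'
#' `Vc = Vcmax C / (C + KC21%O2)`: the carboxylation rate at a CO2
#' concentration `c`, with the apparent Michaelis constant at 21% O2 folding
#' in competitive oxygen inhibition. Used to compare treatments on an
#' equal-enzyme basis (with kcatCO2 standing in for Vcmax).
#'
#' @param v_cmax Maximum carboxylation rate (any rate unit).
#' @param c CO2 concentration(s), same units as `k_c21`.
#' @param k_c21 Apparent Michaelis constant at 21% O2.
#' @return Carboxylation rate(s), units of `v_cmax`.
#' @export
vc_response <- function(v_cmax, c, k_c21) {
  if (any(c(v_cmax, c, k_c21) < 0)) {
    abort("all arguments must be non-negative.", class = "rubiscotherm_domain_error")
  }
  v_cmax * c / (c + k_c21)
}

#' Assimilation per Rubisco catalytic site
#'
#' `(A_N + R_d) / [Rubisco sites]`: gross CO2 fixation expressed as a
#' turnover per catalytic site (s-1), the in vivo analogue of kcatCO2.
#'
#' @param a_n Net assimilation, umol CO2 m-2 s-1.
#' @param r_d Day respiration, umol CO2 m-2 s-1.
#' @param rubisco_sites Rubisco catalytic-site content, umol m-2 (> 0).
#' @return Turnover, s-1.
#' @examples
#' assimilation_per_rubisco(19.2, 1.1, 14.4)
#' @export
assimilation_per_rubisco <- function(a_n, r_d, rubisco_sites) {
  if (any(rubisco_sites <= 0)) {
    abort("`rubisco_sites` must be strictly positive.", class = "rubiscotherm_domain_error")
  }
  (a_n + r_d) / rubisco_sites
}
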