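# Independent oracles used across tests. These deliberately avoid the code
# paths they check: closed-form arithmetic for the Arrhenius and
# Michaelis-Menten expressions, and a damped fixed-point iteration of
# Cc = Ci - A/gm for assimilation at intercellular CO2.

R_CONST <- 8.314

# one-line closed-form recomputation of the exponential temperature response
oracle_arrhenius <- function(value_25, ea_kj, t) {
  value_25 * exp((t - 25) * ea_kj * 1000 / (298 * R_CONST * (273 + t)))
}

# fixed-point solution of A = A_cc(Ci - A/gm), solved robustly as the root
# of g(A) = A - A_cc(Ci - A/gm), which is strictly increasing in A
oracle_assimilation_ci <- function(params, c_i, tol = 1e-12) {
  vapply(c_i, function(ci) {
    g <- function(a) {
      cc <- max(ci - a / params$g_m, 0)
      a - assimilation_cc(params, cc)$a_net
    }
    lo <- -params$r_d - params$v_cmax - params$j_max
    hi <- params$v_cmax + params$j_max
    stats::uniroot(g, c(lo, hi), tol = tol)$root
  }, numeric(1))
}

# random but physiologically plausible FvCB parameter sets
random_fvcb_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fvcb_parameters(
        v_cmax = runif(1, 20, 150),
        j_max = runif(1, 50, 250),
        r_d = runif(1, 0.5, 5),
        g_m = runif(1, 0.05, 0.5),
        gamma_star = runif(1, 20, 70),
        k_m = runif(1, 150, 1100)
      )
    })
  })
}

# default study truth used by fitting tests (noiseless unless stated)
noiseless_truth <- function(seed = 1) synthetic_truth(seed = seed, noise_sd_gas = 0)

cell_truth_row <- function(truth, growth, measurement) {
  dplyr::filter(truth$cells, growth == !!growth, measurement == !!measurement)
}
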