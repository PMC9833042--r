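#' Generating truth for a synthetic gas-exchange study
#'
#' Bundles everything needed to simulate the full 2 growth temperatures x
#' 2 measurement temperatures design: per-treatment Rubisco kinetics,
#' per-cell leaf-level FvCB parameters (with gas-phase Gamma* and Km derived
#' from the kinetics at the measurement temperature), noise levels and the
#' master seed. Defaults are the bundled Arabidopsis treatment means
#' ([arabidopsis_kinetics()], [photosynthesis_defaults()]), additive
#' Gaussian noise with sd 0.2 umol m-2 s-1 on assimilation and 5%
#' multiplicative lognormal noise on in vitro assay rates - magnitudes
#' consistent with the published standard errors.
#'
#' @param cells Per-cell parameter tibble with columns `growth`,
#'   `measurement`, `v_cmax`, `j_max`, `r_d`, `g_m`, `g_s`, `rubisco_sites`.
#' @param kinetics Named list of [rubisco_kinetics()] per growth label.
#' @param noise_sd_gas Additive noise sd on net assimilation,
#'   umol m-2 s-1 (>= 0).
#' @param noise_cv_assay Coefficient of variation of in vitro assay noise
#'   (>= 0).
#' @param ci_ca_ratio Mean intercellular:ambient CO2 drawdown ratio.
#' @param ci_jitter_sd Jitter sd on the drawdown ratio per step.
#' @param o2 Ambient O2 mole fraction, umol mol-1.
#' @param pressure Air pressure, kPa.
#' @param seed Master seed; all generators are pure functions of
#'   (truth, seed).
#' @return An object of class `synthetic_truth`; `$cells` gains `gamma_star`
#'   and `k_m` columns (gas-phase, umol mol-1).
#' @examples
#' truth <- synthetic_truth(seed = 7)
#' truth$cells
#' @export
synthetic_truth <- function(cells = NULL, kinetics = NULL,
                            noise_sd_gas = 0.2, noise_cv_assay = 0.05,
                            ci_ca_ratio = 0.7, ci_jitter_sd = 0.01,
                            o2 = 210000, pressure = 101.325, seed = 1L) {
  if (noise_sd_gas < 0 || noise_cv_assay < 0) {
    abort("noise parameters must be non-negative.", class = "rubiscotherm_input_error")
  }
  if (ci_ca_ratio <= 0 || ci_ca_ratio >= 1) {
    abort("`ci_ca_ratio` must lie in (0, 1).", class = "rubiscotherm_input_error")
  }
  cells <- cells %||% dplyr::select(
    photosynthesis_defaults(),
    "growth", "measurement", "v_cmax", "j_max", "r_d", "g_m", "g_s", "rubisco_sites"
  )
  kinetics <- kinetics %||% {
    labs <- unique(cells$growth)
    setNames(lapply(labs, arabidopsis_kinetics), labs)
  }
  missing_kin <- setdiff(unique(cells$growth), names(kinetics))
  if (length(missing_kin)) {
    abort(sprintf("no kinetics supplied for growth label(s): %s",
                  paste(missing_kin, collapse = ", ")),
          class = "rubiscotherm_input_error")
  }
  sol <- gas_solubility()
  cells <- dplyr::mutate(
    cells,
    purrr::map2_dfr(.data$growth, .data$measurement, function(g, t) {
      kt <- kinetics_at_temperature(kinetics[[g]], t)
      o_um <- dissolved_concentration(o2, pressure, t, "O2", sol)
      tibble(
        gamma_star = gas_mole_fraction(gamma_star_from_sco(kt$s_co, o_um),
                                       pressure, t, "CO2", sol),
        k_m = gas_mole_fraction(kc_apparent_o2(kt$k_c, kt$k_o, o_um),
                                pressure, t, "CO2", sol)
      )
    })
  )
  structure(
    list(cells = cells, kinetics = kinetics,
         noise_sd_gas = noise_sd_gas, noise_cv_assay = noise_cv_assay,
         ci_ca_ratio = ci_ca_ratio, ci_jitter_sd = ci_jitter_sd,
         o2 = o2, pressure = pressure, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d design cells, seed %d\n", nrow(x$cells), x$seed))
  cat(sprintf("  noise: gas sd %g umol m-2 s-1, assay CV %g\n",
              x$noise_sd_gas, x$noise_cv_assay))
  print(x$cells)
  invisible(x)
}

## CO2 step schedule of the measurement protocol; the 1800 step is used at
## the 30 degC measurement temperature only, and the 400 step repeats.
ca_schedule <- function(measurement) {
  s <- c(400, 200, 150, 100, 75, 50, 300, 400, 400, 500, 750, 1200)
  if (measurement >= 30) c(s, 1800) else s
}

truth_cell <- function(truth, growth, measurement) {
  cell <- dplyr::filter(truth$cells, .data$growth == !!growth,
                        .data$measurement == !!measurement)
  if (nrow(cell) != 1L) {
    abort(sprintf("no design cell for growth '%s' at %g degC.", growth, measurement),
          class = "rubiscotherm_input_error")
  }
  cell
}

## Deterministic per-curve / per-assay seed, kept well below 2^31.
derive_seed <- function(truth, growth, measurement, replicate, stream = 0L) {
  cell_idx <- which(truth$cells$growth == growth &
                      truth$cells$measurement == measurement)
  (truth$seed * 97L + stream * 7919L + cell_idx * 389L + as.integer(replicate) * 13L) %%
    2100000000L
}

#' Simulate one A-Ci gas-exchange curve
#'
#' Walks the measurement protocol's CO2 step schedule, derives intercellular
#' CO2 from ambient CO2 with a jittered constant drawdown ratio, evaluates
#' the forward FvCB model ([assimilation_ci()]) with the cell's generating
#' parameters, and adds Gaussian noise to net assimilation. Identical
#' (truth, cell, replicate) inputs yield identical curves.
#'
#' @param truth A [synthetic_truth()].
#' @param growth Growth label (must exist in `truth$cells`).
#' @param measurement Measurement temperature, degC.
#' @param replicate Replicate (plant) index; shifts the derived seed.
#' @return A [gas_exchange_curve()] with metadata filled from the truth.
#' @export
generate_aci_curve <- function(truth, growth, measurement, replicate = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cell <- truth_cell(truth, growth, measurement)
  params <- fvcb_parameters(cell$v_cmax, cell$j_max, cell$r_d, cell$g_m,
                            cell$gamma_star, cell$k_m)
  c_a <- ca_schedule(measurement)
  seed <- derive_seed(truth, growth, measurement, replicate, stream = 0L)
  sim <- withr::with_seed(seed, {
    ratio <- pmin(pmax(truth$ci_ca_ratio + rnorm(length(c_a), 0, truth$ci_jitter_sd),
                       0.5), 0.95)
    c_i <- ratio * c_a
    list(
      c_i = c_i,
      g_s = pmax(cell$g_s * (1 + rnorm(length(c_a), 0, 0.05)), 1e-3),
      a_net = assimilation_ci(params, c_i)$a_net +
        rnorm(length(c_a), 0, truth$noise_sd_gas)
    )
  })
  gas_exchange_curve(
    tibble(
      c_a = c_a, c_i = sim$c_i, a_net = sim$a_net, g_s = sim$g_s,
      t_leaf = measurement, pressure = truth$pressure
    ),
    plant_id = sprintf("%s_T%g_rep%d", growth, measurement, replicate),
    growth = growth, measurement = measurement,
    r_d = cell$r_d, rubisco_sites = cell$rubisco_sites
  )
}

#' Simulate an in vitro Rubisco temperature assay
#'
#' For each assay temperature and kinetic parameter, draws `reps` replicate
#' measurements around the Arrhenius temperature response of the treatment's
#' generating kinetics, with mean-one multiplicative lognormal noise of the
#' truth's assay CV.
#'
#' @param truth A [synthetic_truth()].
#' @param growth Growth label.
#' @param temps Assay temperatures, degC.
#' @param reps Replicates per (temperature, parameter); >= 1.
#' @return Tibble with columns `growth`, `parameter`, `temperature`,
#'   `replicate`, `value`.
#' @export
generate_kinetic_assay <- function(truth, growth, temps = c(10, 15, 20, 25, 30, 35),
                                   reps = 5L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (reps < 1L) {
    abort("`reps` must be >= 1.", class = "rubiscotherm_input_error")
  }
  kin <- truth$kinetics[[growth]]
  if (is.null(kin)) {
    abort(sprintf("no kinetics for growth label '%s'.", growth),
          class = "rubiscotherm_input_error")
  }
  cv <- truth$noise_cv_assay
  sdlog <- sqrt(log(1 + cv^2))
  grid <- tidyr::expand_grid(
    parameter = c("kcat_co2", "s_co", "k_c", "k_o"),
    temperature = temps,
    replicate = seq_len(reps)
  )
  seed <- (truth$seed * 97L + match(growth, names(truth$kinetics)) * 104729L) %% 2100000000L
  withr::with_seed(seed, {
    noise <- if (cv > 0) exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog)) else rep(1, nrow(grid))
  })
  dplyr::mutate(
    grid,
    growth = growth,
    value = purrr::map2_dbl(.data$parameter, .data$temperature,
                            function(p, t) arrhenius_value(kin[[p]], t)) * noise,
    .before = 1
  )
}

#' Simulate and write a complete gas-exchange study
#'
#' Generates `n_replicates` A-Ci curves for every design cell plus one
#' temperature-assay table per growth treatment, writes them as delimited
#' text into `dir`, and records the generating truth and seed in a YAML
#' manifest (`manifest.yml`).
#'
#' @param truth A [synthetic_truth()].
#' @param n_replicates Curves (plants) per design cell; >= 1.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble listing the files written (`file`, `kind`).
#' @export
generate_study_dataset <- function(truth, n_replicates = 5L, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_replicates < 1L) {
    abort("`n_replicates` must be >= 1.", class = "rubiscotherm_input_error")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, mode = 2L) != 0L) {
    abort(sprintf("cannot write to output directory '%s'.", dir),
          class = "rubiscotherm_io_error")
  }
  files <- purrr::pmap_dfr(
    tidyr::expand_grid(cell = seq_len(nrow(truth$cells)), rep = seq_len(n_replicates)),
    function(cell, rep) {
      g <- truth$cells$growth[cell]
      m <- truth$cells$measurement[cell]
      curve <- generate_aci_curve(truth, g, m, rep)
      path <- file.path(dir, sprintf("aci_%s_T%g_rep%d.tsv", g, m, rep))
      write_gas_exchange(curve, path)
      tibble(file = path, kind = "curve")
    }
  )
  assays <- purrr::map_dfr(names(truth$kinetics), function(g) {
    tbl <- generate_kinetic_assay(truth, g)
    path <- file.path(dir, sprintf("assay_%s.tsv", g))
    readr::write_tsv(tbl, path)
    tibble(file = path, kind = "assay")
  })
  manifest <- list(
    package = "rubiscotherm",
    version = as.character(utils::packageVersion("rubiscotherm")),
    seed = truth$seed,
    n_replicates = as.integer(n_replicates),
    noise_sd_gas = truth$noise_sd_gas,
    noise_cv_assay = truth$noise_cv_assay,
    ci_ca_ratio = truth$ci_ca_ratio,
    ci_jitter_sd = truth$ci_jitter_sd,
    o2 = truth$o2,
    pressure = truth$pressure,
    cells = purrr::transpose(lapply(truth$cells, function(col) as.list(col)))
  )
  manifest_path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(dplyr::bind_rows(files, assays,
                             tibble(file = manifest_path, kind = "manifest")))
}

#' Read a study manifest back
#'
#' @param path Path to a `manifest.yml` written by
#'   [generate_study_dataset()].
#' @return List with the manifest scalars and the `cells` truth tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("manifest not found: %s", path), class = "rubiscotherm_io_error")
  }
  m <- yaml::read_yaml(path)
  m$cells <- dplyr::bind_rows(lapply(m$cells, as_tibble))
  m
}
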