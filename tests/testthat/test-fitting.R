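test_that("the split fit inverts a noiseless cold-grown 10 degC curve exactly", {
  truth <- noiseless_truth()
  curve <- generate_aci_curve(truth, "10C", 10)
  fit <- fit_aci(curve, arabidopsis_kinetics("10C"))
  cell <- cell_truth_row(truth, "10C", 10)
  expect_equal(fit$params$v_cmax, cell$v_cmax, tolerance = 1e-4)
  expect_equal(fit$params$j_max, cell$j_max, tolerance = 1e-4)
  expect_equal(fit$params$g_m, cell$g_m, tolerance = 1e-4)
  expect_lt(fit$criterion, 1e-6)
  expect_lt(fit$rmse, 1e-6)
  expect_gte(min(fit$n_points_per_limb), 3)
})

test_that("the chosen transition brackets the true limb crossover on noiseless data", {
  truth <- noiseless_truth()
  curve <- generate_aci_curve(truth, "10C", 10)
  cell <- cell_truth_row(truth, "10C", 10)
  p <- fvcb_parameters(cell$v_cmax, cell$j_max, cell$r_d, cell$g_m,
                       cell$gamma_star, cell$k_m)
  lim <- assimilation_ci(p, sort(curve$c_i))$limitation
  true_last_rubisco <- max(which(lim == "rubisco"))
  fit <- fit_aci(curve, arabidopsis_kinetics("10C"))
  ci_sorted <- sort(curve$c_i)
  # transition Ci must separate (up to one protocol step) the two true limbs
  expect_gte(fit$transition_ci, ci_sorted[true_last_rubisco - 1])
  expect_lte(fit$transition_ci, ci_sorted[min(true_last_rubisco + 1, length(lim))])
})

test_that("fit_aci estimates are invariant to record order and to duplicated steps", {
  truth <- noiseless_truth()
  curve <- generate_aci_curve(truth, "30C", 30)
  kin <- arabidopsis_kinetics("30C")
  base <- fit_aci(curve, kin)

  shuffled <- curve[withr::with_seed(5, sample(nrow(curve))), ]
  attr(shuffled, "meta") <- curve_meta(curve)
  class(shuffled) <- class(curve)
  again <- fit_aci(shuffled, kin)
  expect_equal(again$params$v_cmax, base$params$v_cmax, tolerance = 1e-10)
  expect_equal(again$params$j_max, base$params$j_max, tolerance = 1e-10)
  expect_equal(again$params$g_m, base$params$g_m, tolerance = 1e-10)

  # duplicating the repeated 400-step rows only reweights identical
  # residual-zero points: noiseless estimates are unchanged
  dup_rows <- which(curve$c_a == 400)
  duped <- dplyr::bind_rows(curve, curve[dup_rows, ])
  attr(duped, "meta") <- curve_meta(curve)
  class(duped) <- class(curve)
  fit_dup <- fit_aci(duped, kin)
  expect_equal(fit_dup$params$v_cmax, base$params$v_cmax, tolerance = 1e-6)
  expect_equal(fit_dup$params$j_max, base$params$j_max, tolerance = 1e-6)
})

test_that("fit_aci rejects short curves and missing respiration", {
  truth <- noiseless_truth()
  curve <- generate_aci_curve(truth, "10C", 10)
  short <- curve[1:5, ]
  attr(short, "meta") <- curve_meta(curve)
  class(short) <- class(curve)
  expect_error(fit_aci(short, arabidopsis_kinetics("10C")),
               class = "rubiscotherm_input_error")
  expect_error(fit_aci(curve, arabidopsis_kinetics("10C"), r_d = -1),
               class = "rubiscotherm_input_error")
})

test_that("tidy and glance expose the split-fit results", {
  truth <- noiseless_truth()
  fit <- fit_aci(generate_aci_curve(truth, "30C", 30), arabidopsis_kinetics("30C"))
  td <- tidy(fit)
  expect_true(all(c("v_cmax", "j_max", "g_m", "gm_rubisco", "gm_rubp") %in% td$term))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_gte(gl$n_rubisco, 3)
  expect_gte(gl$n_rubp, 3)
})

test_that("fit_mm_kc21 inverts a noiseless Rubisco-limited curve exactly", {
  gamma_star <- 35
  cc <- seq(50, 600, length.out = 12)
  d <- tibble::tibble(c_c = cc, a_net = 108.1 * (cc - gamma_star) / (cc + 54.9) - 3.6)
  fit <- fit_mm_kc21(d, gamma_star = gamma_star, r_d = 3.6)
  expect_equal(fit$kc21_apparent, 54.9, tolerance = 1e-6)
  expect_equal(fit$vmax_term, 108.1, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # per-site normalisation turns the rate term into an in vivo kcat
  fit_sites <- fit_mm_kc21(d, gamma_star = gamma_star, r_d = 3.6,
                           rubisco_sites = 14.4, normalise_by_sites = TRUE)
  expect_equal(fit_sites$kcat_in_vivo, 108.1 / 14.4, tolerance = 1e-6)
})

test_that("fit_mm_kc21 stays unbiased under noise", {
  gamma_star <- 35
  cc <- seq(50, 600, length.out = 12)
  ests <- vapply(1:50, function(i) {
    withr::with_seed(1000 + i, {
      a <- 108.1 * (cc - gamma_star) / (cc + 54.9) - 3.6 + rnorm(length(cc), 0, 0.2)
    })
    fit_mm_kc21(tibble::tibble(c_c = cc, a_net = a), gamma_star, r_d = 3.6)$kc21_apparent
  }, numeric(1))
  expect_lt(abs(median(ests) / 54.9 - 1), 0.05)
})

test_that("fit_mm_kc21 rejects degenerate and invalid chloroplastic CO2", {
  gamma_star <- 35
  flat <- tibble::tibble(c_c = rep(gamma_star, 8), a_net = rep(-3.6, 8))
  expect_error(fit_mm_kc21(flat, gamma_star, r_d = 3.6),
               class = "rubiscotherm_fit_error")
  neg <- tibble::tibble(c_c = c(-1, 50, 100, 200, 300, 400), a_net = 1:6)
  expect_error(fit_mm_kc21(neg, gamma_star, r_d = 3.6),
               class = "rubiscotherm_input_error")
  expect_error(fit_mm_kc21(neg[2:6, ], gamma_star, r_d = 3.6, normalise_by_sites = TRUE),
               class = "rubiscotherm_input_error")
})

test_that("initial_slope recovers exact lines and approximates the MM chord", {
  line <- tibble::tibble(c_c = c(10, 20, 30), a_net = 0.1 * c(10, 20, 30) + 1)
  out <- suppressWarnings(initial_slope(line, c_c_max = 30))
  expect_equal(out$slope, 0.1, tolerance = 1e-12)
  expect_equal(out$se, 0, tolerance = 1e-10)

  # low-CO2 chord of a noiseless saturating curve is close to the
  # carboxylation-efficiency prediction vmax/(kc21 + gamma*)
  gamma_star <- 3; kc21 <- 55; vmax <- 100
  cc <- seq(4, 0.1 * kc21, length.out = 6)
  d <- tibble::tibble(c_c = cc, a_net = vmax * (cc - gamma_star) / (cc + kc21))
  sl <- initial_slope(d, c_c_max = max(cc))
  expect_lt(abs(sl$slope / (vmax / (kc21 + gamma_star)) - 1), 0.10)

  expect_error(initial_slope(line, c_c_max = 15), class = "rubiscotherm_input_error")
})

test_that("percent_difference matches independent arithmetic in both modes", {
  expect_equal(percent_difference(14.4, 8.9, "reduction"), 100 * (14.4 - 8.9) / 14.4,
               tolerance = 1e-15)
  expect_equal(percent_difference(24.6, 19.8, "excess"), 100 * (24.6 - 19.8) / 19.8,
               tolerance = 1e-15)
  expect_identical(percent_difference(5, 5, "reduction"), 0)
  expect_identical(percent_difference(5, 5, "excess"), 0)
  expect_error(percent_difference(0, 5, "reduction"), class = "rubiscotherm_domain_error")
  expect_error(percent_difference(5, 0, "excess"), class = "rubiscotherm_domain_error")
})

test_that("summarize_fits and contrast_growth reproduce group means and contrasts", {
  d <- tibble::tibble(
    growth = rep(c("10C", "30C"), each = 4),
    measurement = rep(c(10, 30), times = 4),
    v_cmax = c(50, 100, 60, 110, 40, 95, 44, 99)
  )
  s <- summarize_fits(d, growth, measurement)
  expect_identical(nrow(s), 4L)
  cold10 <- dplyr::filter(s, growth == "10C", measurement == 10)
  expect_equal(cold10$mean, 55)
  expect_equal(cold10$se, sd(c(50, 60)) / sqrt(2))
  ct <- contrast_growth(s, mode = "excess")
  expect_identical(nrow(ct), 2L)
  got <- dplyr::filter(ct, measurement == 10)$percent
  expect_equal(got, 100 * (55 - 42) / 42, tolerance = 1e-12)
})
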