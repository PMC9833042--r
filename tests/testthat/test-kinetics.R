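test_that("arrhenius_value is the identity at 25 degC for any activation energy", {
  for (ea in c(-40, -5, 0, 5.47, 54.8, 120)) {
    tr <- temperature_response(3.31, ea)
    expect_identical(arrhenius_value(tr, 25), 3.31)
  }
})

test_that("arrhenius_value matches the closed-form oracle and printed-style values", {
  # cold-grown KC extrapolated to 35 degC
  kc_cold <- temperature_response(11.8, 54.8)
  expect_equal(arrhenius_value(kc_cold, 35), oracle_arrhenius(11.8, 54.8, 35),
               tolerance = 1e-12)
  expect_equal(arrhenius_value(kc_cold, 35), 24.2, tolerance = 0.005)
  # warm-grown KC at 35 degC
  expect_equal(arrhenius_value(temperature_response(11.4, 40.4), 35), 19.4,
               tolerance = 0.005)
  # vectorised over temperature
  temps <- c(-10, 0, 10, 25, 40, 60)
  expect_equal(arrhenius_value(kc_cold, temps),
               oracle_arrhenius(11.8, 54.8, temps), tolerance = 1e-12)
})

test_that("the cold:warm KC ratio at 35 degC reproduces the ~26% divergence", {
  cold <- arrhenius_value(arabidopsis_kinetics("10C")$k_c, 35)
  warm <- arrhenius_value(arabidopsis_kinetics("30C")$k_c, 35)
  expect_gt(cold / warm, 1.245)
  expect_lt(cold / warm, 1.26)
})

test_that("arrhenius_value is monotone in temperature with the sign of Ea", {
  temps <- seq(-10, 60, by = 2)
  up <- arrhenius_value(temperature_response(1, 50), temps)
  down <- arrhenius_value(temperature_response(80, -22), temps)
  flat <- arrhenius_value(temperature_response(5, 0), temps)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
  expect_true(all(flat == 5))
  expect_true(all(up > 0) && all(down > 0))
})

test_that("out-of-range temperatures and bad constructor inputs error", {
  tr <- temperature_response(1, 50)
  expect_error(arrhenius_value(tr, -20), class = "rubiscotherm_domain_error")
  expect_error(arrhenius_value(tr, 75), class = "rubiscotherm_domain_error")
  expect_error(temperature_response(-1, 50), class = "rubiscotherm_input_error")
  expect_error(temperature_response(1, 50, se_25 = -0.1),
               class = "rubiscotherm_input_error")
})

test_that("kinetics_at_temperature returns the 25 degC values unchanged at t = 25", {
  k10 <- arabidopsis_kinetics("10C")
  at25 <- kinetics_at_temperature(k10, 25)
  expect_equal(unlist(at25[, c("kcat_co2", "s_co", "k_c", "k_o")]),
               c(kcat_co2 = 3.31, s_co = 75.1, k_c = 11.8, k_o = 275.6))
  at35 <- kinetics_at_temperature(arabidopsis_kinetics("30C"), 35)
  expect_equal(at35$k_c, oracle_arrhenius(11.4, 40.4, 35), tolerance = 1e-12)
})

test_that("fit_arrhenius inverts noiseless forward data for every bundled treatment", {
  tbl <- arabidopsis_kinetics()
  temps <- c(10, 15, 20, 25, 30, 35)
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    d <- tibble::tibble(
      temperature = temps,
      value = oracle_arrhenius(row$value_25, row$ea_kj_mol, temps)
    )
    fit <- fit_arrhenius(d)
    expect_equal(fit$tr$value_25, row$value_25, tolerance = 1e-6)
    expect_equal(fit$tr$e_a, row$ea_kj_mol, tolerance = 1e-6)
  }
})

test_that("fit_arrhenius handles flat data and rejects deficient input", {
  flat <- tibble::tibble(temperature = c(10, 20, 30, 40), value = rep(2.5, 4))
  fit <- fit_arrhenius(flat)
  expect_equal(fit$tr$e_a, 0, tolerance = 1e-8)
  expect_equal(fit$tr$value_25, 2.5, tolerance = 1e-8)
  expect_error(fit_arrhenius(tibble::tibble(temperature = c(10, 30), value = c(1, 2))),
               class = "rubiscotherm_input_error")
  expect_error(
    fit_arrhenius(tibble::tibble(temperature = c(10, 20, 30), value = c(1, -2, 3))),
    class = "rubiscotherm_input_error"
  )
  td <- tidy(fit)
  expect_identical(td$term, c("value_25", "e_a"))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("kc_apparent_o2 matches independent arithmetic and its bounds", {
  expect_identical(kc_apparent_o2(11.8, 275.6, 0), 11.8)
  expect_equal(kc_apparent_o2(11.8, 275.6, 253), 11.8 * (1 + 253 / 275.6),
               tolerance = 1e-15)
  expect_equal(kc_apparent_o2(11.8, 275.6, 253), 22.63, tolerance = 1e-3)
  expect_equal(kc_apparent_o2(11.4, 259.7, 253), 22.5, tolerance = 1e-2)
  withr::with_seed(42, {
    for (i in 1:25) {
      kc <- runif(1, 5, 30); ko <- runif(1, 100, 500); o <- runif(1, 0, 400)
      expect_gte(kc_apparent_o2(kc, ko, o), kc)
      expect_equal(kc_apparent_o2(kc, ko, o), kc * (1 + o / ko), tolerance = 1e-15)
    }
  })
  expect_error(kc_apparent_o2(11.8, 0, 253), class = "rubiscotherm_domain_error")
})

test_that("gamma_star_from_sco matches 0.5 O / SC/O and is monotone in SC/O", {
  expect_equal(gamma_star_from_sco(78, 253), 0.5 * 253 / 78, tolerance = 1e-15)
  expect_equal(gamma_star_from_sco(78, 253), 1.62, tolerance = 1e-2)
  expect_identical(gamma_star_from_sco(78, 0), 0)
  sco <- seq(60, 120, by = 5)
  expect_true(all(diff(gamma_star_from_sco(sco, 253)) < 0))
  expect_error(gamma_star_from_sco(0, 253), class = "rubiscotherm_domain_error")
  expect_error(gamma_star_from_sco(-5, 253), class = "rubiscotherm_domain_error")
})

test_that("rubisco_kinetics enforces KO > KC and bundles four responses", {
  expect_error(
    rubisco_kinetics(
      temperature_response(3, 50), temperature_response(80, -20),
      temperature_response(300, 50), temperature_response(12, 5)
    ),
    class = "rubiscotherm_input_error"
  )
  k <- arabidopsis_kinetics("20C")
  expect_s3_class(k, "rubisco_kinetics")
  expect_identical(k$label, "20C")
  expect_identical(k$k_c$value_25, 11.5)
})
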