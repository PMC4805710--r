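test_that("power-law fit is exact on noiseless sphere data", {
  d <- c(50, 100, 200)
  fit <- fit_massmob(massmob_data(d, sphere_mass(d, 1)))
  expect_equal(fit$D_mm, 3, tolerance = 1e-10)
  expect_equal(fit$k, pi / 6 * 1000, tolerance = 1e-10)
  expect_true(fit$ci_defined)
  # prediction is exact at the fitted points
  expect_equal(mass_at(fit, d), sphere_mass(d, 1), tolerance = 1e-12)
})

test_that("two-point data give the closed-form exponent with undefined CI", {
  d <- c(60, 240); m <- c(2e-19, 9e-18)
  expect_warning(fit <- fit_massmob(massmob_data(d, m)), "CI is undefined")
  expect_equal(fit$D_mm, log(m[2] / m[1]) / log(d[2] / d[1]))
  expect_false(fit$ci_defined)
  expect_true(all(is.na(fit$D_mm_ci)))
})

test_that("fit rejects degenerate inputs", {
  expect_error(massmob_data(100, 1e-18), "at least 2")
  expect_error(massmob_data(c(100, 200), c(-1, 1)), "positive")
  df <- data.frame(diameter_nm = c(100, 100), mass_kg = c(1e-18, 2e-18))
  expect_error(fit_massmob(df), "degenerate")
})

test_that("mass_at is a monotone power law and validates input", {
  fit <- sphere_massmob(8.96)
  expect_equal(mass_at(fit, 100), sphere_mass(100, 8.96))
  expect_true(mass_at(fit, 120) > mass_at(fit, 80))
  expect_error(mass_at(fit, -5), "positive")
  # hand arithmetic: (pi/6)(5.74e-8)^3 * 8960 kg/m^3
  expect_equal(sphere_mass(57.4, 8.96), 8.87e-19, tolerance = 1e-3)
  expect_equal(sphere_mass(1e9, 1e-3), pi / 6)  # 1 m sphere at 1 kg/m^3
})

test_that("recovered exponent lies in its own 95% CI for noisy replicates", {
  set.seed(42)
  truth <- 2.10
  hits <- 0L
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    d <- 10^seq(log10(40), log10(360), length.out = 20)
    m <- 2.9e-4 * (d * 1e-9)^truth * rlnorm(20, 0, 0.05)
    fit <- fit_massmob(data.frame(diameter_nm = d, mass_kg = m))
    if (fit$D_mm_ci[1] <= truth && truth <= fit$D_mm_ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("mass pipeline matches lognormal moment closed forms", {
  grid <- log_grid(5, 3000, 192)
  # D_mm = 3 sphere: c_m = c_N k CMD^3 exp(4.5 ln^2 GSTD), verified against
  # independent numeric integration
  md <- number_to_mass_distribution(make_lognormal(1e6, 100, 1.6, grid),
                                    sphere_massmob(1))
  oracle <- lognormal_moment_total(1e6, 100, 1.6, pi / 6 * 1000, 3) * 1e12
  expect_equal(total_mass_concentration(md), oracle, tolerance = 0.01)
  expect_equal(oracle, 1e6 * pi / 6 * 1000 * (100e-9)^3 *
                 exp(4.5 * log(1.6)^2) * 1e12, tolerance = 1e-6)

  # general exponent: c_m = c_N k CMD^D exp(D^2 ln^2 GSTD / 2)
  fit <- structure(list(k = 2.9e-4, D_mm = 2.08), class = "massmob")
  md2 <- number_to_mass_distribution(make_lognormal(2.58e6, 115.1, 1.67, grid),
                                     fit)
  closed <- 2.58e6 * 2.9e-4 * (115.1e-9)^2.08 *
    exp(2.08^2 * log(1.67)^2 / 2) * 1e12
  expect_equal(total_mass_concentration(md2), closed, tolerance = 0.01)
  expect_equal(closed,
               lognormal_moment_total(2.58e6, 115.1, 1.67, 2.9e-4, 2.08) * 1e12,
               tolerance = 1e-6)
})

test_that("mass distribution is linear in the number density", {
  fit <- sphere_massmob(2)
  d1 <- make_lognormal(1e6, 80, 1.5)
  d2 <- make_lognormal(3e6, 80, 1.5)
  m1 <- total_mass_concentration(number_to_mass_distribution(d1, fit))
  m2 <- total_mass_concentration(number_to_mass_distribution(d2, fit))
  expect_equal(m2, 3 * m1)
  dsum <- nsd(d1$diameter_nm, d1$dndlogdp + d2$dndlogdp)
  expect_equal(total_mass_concentration(number_to_mass_distribution(dsum, fit)),
               m1 + m2)
})

test_that("delta distribution total mass equals N times the particle mass", {
  spike <- make_lognormal(5e5, 120, 1.0)
  fit <- sphere_massmob(8.96)
  expect_equal(total_mass_concentration(number_to_mass_distribution(spike, fit)),
               5e5 * mass_at(fit, summary(spike)$CMD) * 1e12)
  zero <- nsd(c(10, 100), c(0, 0))
  md <- number_to_mass_distribution(zero, fit)
  expect_true(all(md$dmdlogdp == 0))
})

test_that("mg/m^3 to ug/cm^3 conversion reproduces the Ag_1 mass dose", {
  expect_equal(alidose:::MG_M3_TO_UG_CM3, 1e-3)
  expect_equal(round(mass_dose(0.87, exposure_config()), 1), 1.4)
})

test_that("synthetic generator feeds the fit with a recoverable truth", {
  scn <- scenario(seed = 3,
                  massmob = list(k = 2.9e-4, D_mm = 2.18, noise_sigma = 0,
                                 n = 15, d_range = c(40, 360)))
  fit <- fit_massmob(gen_massmob(scn))
  expect_equal(fit$D_mm, 2.18, tolerance = 1e-10)
  expect_equal(fit$k, 2.9e-4, tolerance = 1e-8)
})
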