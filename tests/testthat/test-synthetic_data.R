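test_that("generators are deterministic given (seed, scenario)", {
  scn <- scenario(seed = 51)
  expect_equal(gen_spectrum(scn), gen_spectrum(scn))
  expect_equal(gen_massmob(scn), gen_massmob(scn), ignore_attr = TRUE)
  expect_equal(gen_primaries(scn)$diameter_nm,
               gen_primaries(scn)$diameter_nm)
  expect_false(identical(gen_massmob(scn, seed = 52)$mass_kg,
                         gen_massmob(scn, seed = 53)$mass_kg))
})

test_that("spectrum generator emulates the stated exposure parameters", {
  scn <- scenario(seed = 54,
                  aerosol = list(c_N = 14.82e6, CMD = 141.9, GSTD = 1.87))
  s <- summary(gen_spectrum(scn, grid = log_grid(10, 2000, 96)))
  expect_equal(s$c_N, 14.82e6, tolerance = 0.02)
  expect_equal(s$CMD, 141.9, tolerance = 0.02)
  expect_equal(s$GSTD, 1.87, tolerance = 0.02)

  # zero-noise limit is the exact discretized lognormal
  exact <- gen_spectrum(scn, noise = "none")
  expect_equal(exact$dndlogdp,
               make_lognormal(14.82e6, 141.9, 1.87)$dndlogdp)

  # two seeds differ in noise but share the expectation
  s1 <- summary(gen_spectrum(scn, seed = 1))
  s2 <- summary(gen_spectrum(scn, seed = 2))
  expect_equal(s1$c_N, s2$c_N, tolerance = 0.05)
})

test_that("mass-mobility generator carries its ground truth", {
  scn <- scenario(seed = 55,
                  massmob = list(k = 1e-4, D_mm = 2.2, noise_sigma = 0,
                                 n = 12, d_range = c(40, 360)))
  d <- gen_massmob(scn)
  expect_equal(unname(attr(d, "truth")["D_mm"]), 2.2)
  fit <- fit_massmob(d)
  expect_equal(fit$D_mm, 2.2, tolerance = 1e-10)

  # sphere spec equals the sphere-mass path
  scn3 <- scenario(seed = 56,
                   massmob = list(k = pi / 6 * 1000, D_mm = 3,
                                  noise_sigma = 0, n = 10,
                                  d_range = c(50, 300)))
  d3 <- gen_massmob(scn3)
  expect_equal(d3$mass_kg, sphere_mass(d3$diameter_nm, 1), tolerance = 1e-12)
})

test_that("primary generator spans monodisperse to lognormal", {
  mono <- scenario(seed = 57, primaries = list(gm_nm = 5, gsd = 1, n = 50,
                                               material = "X",
                                               bulk_density_g_cm3 = 1))
  expect_equal(gen_primaries(mono)$diameter_nm, rep(5, 50))
  big <- scenario(seed = 58, primaries = list(gm_nm = 4.71, gsd = 1.22,
                                              n = 1e5, material = "Pd",
                                              bulk_density_g_cm3 = 12.02))
  expect_equal(sauter_diameter(gen_primaries(big)),
               4.71 * exp(2.5 * log(1.22)^2), tolerance = 0.01)
})

test_that("wafer-image generator returns ground truth alongside images", {
  blank <- scenario(seed = 59,
                    deposition = list(efficiency = 0.36, n_images = 2,
                                      mean_disks = 0, disk_radius_px = 3,
                                      speck_rate = 0, image_size = 128))
  w <- gen_wafer_images(blank)
  expect_equal(w$truth, c(0L, 0L))
  # a fixed threshold is needed on particle-free frames (Otsu always splits)
  expect_equal(vapply(w$images, count_particles, integer(1),
                      threshold = 0.5), c(0L, 0L))
})

test_that("response generator censors at the LOD and records its slope", {
  scn <- scenario(seed = 60,
                  response = list(baseline = 1, slope = 0, metric = "m",
                                  noise_sd = 0.05, lod = 0.05,
                                  replicates = 3))
  doses <- data.frame(label = c("a", "b", "c"), dose_N = c(1, 2, 3) * 1e8,
                      dose_m = c(1, 2, 3), dose_SA = c(1, 2, 3))
  tab <- gen_responses(scn, doses)
  expect_equal(attr(tab, "true_slope"), 0)
  expect_true(all(tab$material[tab$exposure_label == "control"] == "control"))

  # an extreme negative slope censors the high-dose levels
  cens <- scenario(seed = 61,
                   response = list(baseline = 1, slope = -0.5, metric = "m",
                                   noise_sd = 0.01, lod = 0.5,
                                   replicates = 3))
  tab2 <- gen_responses(cens, doses)
  expect_true(all(tab2$below_LOD[tab2$dose_m == 3 &
                                   tab2$material != "control"]))

  # a Cu-like viability decline is detected by the tier-3 regression
  det <- scenario(seed = 62,
                  response = list(baseline = 1, slope = -0.05, metric = "m",
                                  noise_sd = 0.05, lod = 0.01,
                                  replicates = 4))
  doses2 <- data.frame(label = letters[1:5], dose_N = (1:5) * 1e8,
                       dose_m = c(0.5, 1, 2, 5, 10),
                       dose_SA = (1:5) / 2)
  tab3 <- gen_responses(det, doses2)
  r <- tox_tier3(tab3, "WST-1", "SAEC", dose_metric = "m")
  expect_true(r$significant)
  expect_equal(r$slope, -0.05, tolerance = 0.3)
})
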