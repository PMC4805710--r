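test_that("tier 1 pools exposed rows and tests the mean ratio against 1", {
  flat <- make_responses(rep(1, 10))
  r <- tox_tier1(flat, "WST-1", "SAEC")
  expect_equal(r$mean_ratio, 1)
  expect_false(r$significant)

  set.seed(31)
  dec <- make_responses(rnorm(30, 0.8, 0.05))
  r2 <- tox_tier1(dec, "WST-1", "SAEC")
  expect_true(r2$significant)
  expect_lt(r2$p_vs_unity, 0.001)
  expect_true(r2$ci95[1] <= r2$mean_ratio && r2$mean_ratio <= r2$ci95[2])
})

test_that("a clear decrease is detected in nearly all replicates", {
  set.seed(32)
  hits <- sum(replicate(300, {
    tox_tier1(make_responses(rnorm(30, 0.8, 0.05)), "WST-1",
              "SAEC")$p_vs_unity < 0.001
  }))
  expect_gte(hits / 300, 0.99)
})

test_that("tier 1 type-I error is calibrated at the nominal 5%", {
  set.seed(33)
  fp <- sum(replicate(2000, {
    tox_tier1(make_responses(abs(rnorm(10, 1, 0.1))), "WST-1",
              "SAEC")$significant
  }))
  expect_equal(fp / 2000, 0.05, tolerance = 0.02 / 0.05)
})

test_that("tier 2 differentiates materials and flags all-LOD groups", {
  set.seed(34)
  tab <- rbind(
    make_responses(rnorm(8, 0.9, 0.05), material = "Cu"),
    make_responses(rnorm(8, 1.1, 0.05), material = "Ag"),
    make_responses(rep(NA_real_, 4), material = "Pd", below_LOD = TRUE))
  r <- tox_tier2(tab, "WST-1", "SAEC")
  expect_named(r, c("Cu", "Ag", "Pd"))
  expect_true(r$Cu$evaluable && r$Ag$evaluable)
  expect_false(r$Pd$evaluable)
  expect_match(r$Pd$reason, "LOD")

  # single-material table degenerates to tier 1
  solo <- make_responses(rnorm(10, 0.95, 0.08), material = "Cu")
  expect_equal(tox_tier2(solo, "WST-1", "SAEC")$Cu$p_vs_unity,
               tox_tier1(solo, "WST-1", "SAEC")$p_vs_unity)
})

test_that("groups drawn from one distribution are indistinguishable", {
  set.seed(35)
  agree <- sum(replicate(200, {
    tab <- rbind(make_responses(rnorm(10, 1, 0.1), material = "Cu"),
                 make_responses(rnorm(10, 1, 0.1), material = "Ag"))
    r <- tox_tier2(tab, "WST-1", "SAEC")
    xor(r$Cu$significant, r$Ag$significant)
  }))
  expect_lte(agree / 200, 0.15)
})

test_that("tier 3 recovers a noiseless linear dose response exactly", {
  dose <- c(0.5, 1, 2, 4, 8)
  tab <- make_responses(1 - 0.01 * dose, dose = dose)
  r <- tox_tier3(tab, "WST-1", "SAEC", dose_metric = "m")
  expect_equal(r$slope, -0.01, tolerance = 1e-12)
  expect_true(r$significant)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
})

test_that("tier 3 slope equals the closed-form OLS slope", {
  set.seed(36)
  dose <- rep(c(1, 2, 5, 10), each = 3)
  y <- 1 - 0.02 * dose + rnorm(12, 0, 0.05)
  tab <- make_responses(y, dose = dose)
  r <- tox_tier3(tab, "WST-1", "SAEC", dose_metric = "N")
  expect_equal(r$slope, ols_slope(dose, y), tolerance = 1e-12)
})

test_that("tier 3 type-I error under the null is 5 +/- 2 percent", {
  set.seed(37)
  dose <- rep(c(1, 2, 4, 8), each = 3)
  fp <- sum(replicate(2000, {
    tab <- make_responses(abs(1 + rnorm(12, 0, 0.1)), dose = dose)
    tox_tier3(tab, "WST-1", "SAEC", dose_metric = "m")$significant
  }))
  expect_equal(fp / 2000, 0.05, tolerance = 0.02 / 0.05)
})

test_that("tier 3 refuses under-determined designs", {
  tab <- make_responses(c(1, 0.9, 0.8, 1.1), dose = c(1, 1, 2, 2))
  r <- tox_tier3(tab, "WST-1", "SAEC", dose_metric = "m")
  expect_false(r$evaluable)
  # missing dose metric (e.g. surface area for Ag) is not evaluable
  tab2 <- make_responses(c(1, 0.9, 0.8, 1.1), dose = c(1, 2, 3, 4))
  tab2$dose_SA <- NA_real_
  expect_false(tox_tier3(tab2, "WST-1", "SAEC", dose_metric = "SA")$evaluable)
})

test_that("tier results ignore row order and dose relabelling", {
  set.seed(38)
  tab <- make_responses(rnorm(12, 0.9, 0.1), dose = rep(1:4, 3))
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(tox_tier1(tab, "WST-1", "SAEC")$p_vs_unity,
               tox_tier1(perm, "WST-1", "SAEC")$p_vs_unity)
  relab <- tab
  relab$dose_N <- relab$dose_N * 100
  expect_equal(tox_tier1(relab, "WST-1", "SAEC")$mean_ratio,
               tox_tier1(tab, "WST-1", "SAEC")$mean_ratio)
})

test_that("below-LOD rows never contribute to any estimate", {
  set.seed(39)
  base <- make_responses(rnorm(10, 0.9, 0.05), dose = rep(c(1, 2, 3, 4, 5), 2))
  spiked <- rbind(base, make_responses(rep(NA_real_, 5),
                                       dose = c(1, 2, 3, 4, 5),
                                       below_LOD = TRUE))
  expect_equal(tox_tier1(spiked, "WST-1", "SAEC")$mean_ratio,
               tox_tier1(base, "WST-1", "SAEC")$mean_ratio)
  expect_equal(tox_tier3(spiked, "WST-1", "SAEC", dose_metric = "m")$slope,
               tox_tier3(base, "WST-1", "SAEC", dose_metric = "m")$slope)
})

test_that("ANCOVA keeps its size under a common slope and detects separation", {
  dose <- rep(c(0, 2, 4, 6, 8, 10), 2)
  n_per <- length(dose)
  sigma <- 0.1
  # analytic SE of the interaction contrast for this balanced design
  sxx <- sum((dose - mean(dose))^2)
  se_diff <- sigma * sqrt(2 / sxx)

  set.seed(40)
  null_sig <- sum(replicate(300, {
    tab <- rbind(
      make_responses(abs(1 - 0.01 * dose + rnorm(n_per, 0, sigma)),
                     dose = dose, material = "Cu"),
      make_responses(abs(1 - 0.01 * dose + rnorm(n_per, 0, sigma)),
                     dose = dose, material = "Ag"))
    tox_ancova(tab, "WST-1", "SAEC", dose_metric = "m")$p_interaction < 0.05
  }))
  expect_gte(1 - null_sig / 300, 0.93)

  set.seed(41)
  power_sig <- sum(replicate(200, {
    tab <- rbind(
      make_responses(abs(1 - 0.01 * dose + rnorm(n_per, 0, sigma)),
                     dose = dose, material = "Cu"),
      make_responses(abs(1 - (0.01 + 5 * se_diff) * dose +
                           rnorm(n_per, 0, sigma)),
                     dose = dose, material = "Ag"))
    tox_ancova(tab, "WST-1", "SAEC", dose_metric = "m")$p_interaction < 0.05
  }))
  expect_gte(power_sig / 200, 0.90)

  expect_error(tox_ancova(make_responses(rnorm(6, 1, 0.1), dose = 1:6),
                          "WST-1", "SAEC", dose_metric = "m"),
               ">= 2 materials")
})
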