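# Standard-curve fitting, area-to-mass conversion, intensity inversion.

test_that("exact standards give the exact line with r^2 = 1", {
  std <- data.frame(conc_ug_per_g = c(0, 1, 2, 5),
                    intensity_per_g = 100 * c(0, 1, 2, 5) + 50)
  cur <- fit_standard_curve(std)
  expect_equal(cur$slope, 100)
  expect_equal(cur$intercept, 50)
  expect_equal(cur$r_squared, 1)
  expect_equal(cur$n_points, 4L)
  expect_equal(unname(coef(cur)), c(100, 50))
  expect_equal(predict(cur, 2), 250)
})

test_that("noiseless single-replicate fit matches the two-point slope", {
  conc <- c(0.5, 1, 2, 4)
  std <- generate_standards(conc, slope = 80, intercept = 30, noise_sd = 0,
                            n_replicates = 1, seed = 3)
  cur <- fit_standard_curve(std)
  ipg <- std$sum_intensity / std$mass_g
  two_point <- (ipg[4] - ipg[1]) / (conc[4] - conc[1])
  expect_equal(cur$slope, two_point)
})

test_that("noisy standards recover slope within 3 SE and match the oracle", {
  std <- generate_standards(seq(0, 5, by = 0.5), slope = 100, intercept = 50,
                            noise_sd = 5, n_replicates = 5, seed = 17)
  cur <- fit_standard_curve(std)
  o <- ols_oracle(std$conc_ug_per_g, std$sum_intensity / std$mass_g)
  expect_equal(cur$slope, o$slope)
  expect_equal(cur$intercept, o$intercept)
  expect_lt(abs(cur$slope - 100), 3 * o$slope_se)
})

test_that("degenerate standards are rejected", {
  expect_error(fit_standard_curve(
    data.frame(conc_ug_per_g = c(0, 1), intensity_per_g = c(1, 2))),
    "3 distinct")
  expect_error(fit_standard_curve(
    data.frame(conc_ug_per_g = rep(2, 5), intensity_per_g = rnorm(5))),
    "3 distinct")
})

test_that("region mass converts um^2 x um x density to grams", {
  expect_equal(region_mass(1e8, 20, 1.04), 2.08e-3)
  expect_equal(region_mass(5e7, 20, 1.04), 1.04e-3)
  expect_equal(region_mass(0, 20, 1.04), 0)
  expect_error(region_mass(-1), "area_um2")
  # linear in area and in thickness
  expect_equal(region_mass(3e7, 20), 3 * region_mass(1e7, 20))
  expect_equal(region_mass(1e7, 40), 2 * region_mass(1e7, 20))
})

test_that("intensity inversion recovers concentration from the line", {
  cur <- fit_standard_curve(data.frame(
    conc_ug_per_g = c(0, 1, 2), intensity_per_g = c(50, 150, 250)))
  # intensity/mass = 250 on curve (100, 50) -> 2 ug/g
  expect_equal(as.numeric(intensity_to_concentration(250 * 0.002, 0.002, cur)), 2)
  # background-only region -> 0
  expect_equal(as.numeric(intensity_to_concentration(50 * 0.002, 0.002, cur)), 0)
  expect_error(intensity_to_concentration(1, 0, cur), "mass_g")
})

test_that("sub-background intensities are flagged, not clamped", {
  cur <- fit_standard_curve(data.frame(
    conc_ug_per_g = c(0, 1, 2), intensity_per_g = c(50, 150, 250)))
  expect_warning(
    conc <- intensity_to_concentration(c(10 * 0.002, 250 * 0.002), 0.002, cur),
    "below zero")
  expect_equal(as.numeric(conc), c((10 - 50) / 100, 2))
  expect_equal(attr(conc, "flagged_negative"), 1L)
})

test_that("calibration round-trips the generator exactly at zero noise", {
  conc <- c(0, 0.25, 0.5, 1, 2, 5)
  std <- generate_standards(conc, slope = 100, intercept = 50, noise_sd = 0,
                            n_replicates = 2, seed = 5)
  cur <- fit_standard_curve(std)
  back <- intensity_to_concentration(std$sum_intensity, std$mass_g, cur)
  expect_equal(as.numeric(back), std$conc_ug_per_g)
})

test_that("concentration is invariant to splitting a region into parts", {
  cur <- fit_standard_curve(data.frame(
    conc_ug_per_g = c(0, 1, 2), intensity_per_g = c(50, 150, 250)))
  # whole region vs mass-weighted recombination of two sub-regions
  m <- c(0.002, 0.006)
  i <- c(250 * 0.002, 250 * 0.006)
  whole <- as.numeric(intensity_to_concentration(sum(i), sum(m), cur))
  parts <- as.numeric(intensity_to_concentration(i, m, cur))
  expect_equal(whole, sum(parts * m) / sum(m))
})
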