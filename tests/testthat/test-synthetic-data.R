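# Synthetic-data generators: exactness at zero noise, seed determinism,
# parameter validation.

test_that("noiseless standards lie exactly on the configured line", {
  std <- generate_standards(c(0, 1, 2), slope = 100, intercept = 0,
                            noise_sd = 0, n_replicates = 1, seed = 1)
  expect_equal(std$sum_intensity / std$mass_g, c(0, 100, 200))

  bg <- generate_standards(0, slope = 100, intercept = 50, noise_sd = 0,
                           n_replicates = 1, seed = 1)
  expect_equal(bg$sum_intensity / bg$mass_g, 50)
})

test_that("noisy standards recover the slope within 3 SE (OLS oracle)", {
  std <- generate_standards(seq(0, 5, length.out = 10), slope = 100,
                            intercept = 50, noise_sd = 5, n_replicates = 5,
                            seed = 42)
  o <- ols_oracle(std$conc_ug_per_g, std$sum_intensity / std$mass_g)
  expect_lt(abs(o$slope - 100), 3 * o$slope_se)
  expect_lt(abs(o$intercept - 50), 3 * o$intercept_se)
})

test_that("perfusion records follow Q* = C*(K_in T + V0) at zero noise", {
  rec <- generate_perfusion_series(0.12, 0.015, 50, times = 120,
                                   noise_cv = 0, n_per_time = 1, seed = 1)
  expect_equal(rec$qstar_ug_per_g, 1.47)

  # impermeant tracer: distribution volume is V0 at every time
  suc <- generate_perfusion_series(0, 0.015, 10, times = c(30, 60, 90, 120),
                                   noise_cv = 0, n_per_time = 2, seed = 1)
  expect_equal(suc$qstar_ug_per_g / suc$cstar_ug_per_ml, rep(0.015, 8))
})

test_that("generators are deterministic in seed and parameters", {
  a <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0.1, seed = 11)
  b <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0.1, seed = 11)
  expect_identical(a, b)
  c <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0.1, seed = 12)
  expect_false(identical(a$qstar_ug_per_g, c$qstar_ug_per_g))

  s1 <- generate_standards(0:3, noise_sd = 5, seed = 11)
  s2 <- generate_standards(0:3, noise_sd = 5, seed = 11)
  expect_identical(s1, s2)
})

test_that("named substreams decouple artifacts from one another", {
  # the standards drawn under a seed do not change when another artifact
  # is generated first from the same top-level seed
  s1 <- generate_standards(0:3, noise_sd = 5, seed = 11)
  invisible(generate_perfusion_series(0.12, 0.015, 50, seed = 11))
  s2 <- generate_standards(0:3, noise_sd = 5, seed = 11)
  expect_identical(s1, s2)
})

test_that("generator rejects invalid parameters", {
  expect_error(generate_standards(0:2, noise_sd = -1), "noise_sd")
  expect_error(generate_perfusion_series(0.12, 0.015, cstar = 0), "cstar")
  expect_error(generate_perfusion_series(0.12, 0.015, cstar = -5), "cstar")
})

test_that("section ground truth is exact with zero blur and noise", {
  sec <- noiseless_section()
  img <- sec$image

  # per-vessel transporter means equal the configured intensities
  for (k in 1:3) {
    expect_equal(mean(img$channels$pgp[sec$vessel_mask == k]),
                 sec$ground_truth$vessels$pgp_intensity[k])
  }
  # endothelial marker nonzero only on vessel tubes
  expect_true(all(img$channels$endothelial[sec$vessel_mask == 0] == 0))
  expect_true(all(img$channels$endothelial[sec$vessel_mask > 0] > 0))

  # lesion amplification is exact: lesion mean / outside mean
  outside <- sec$lesion_mask == 0
  for (k in 1:2) {
    expect_equal(mean(img$channels$r123[sec$lesion_mask == k]) /
                   mean(img$channels$r123[outside]),
                 sec$ground_truth$lesions$fold_r123[k])
  }
})

test_that("null lesion amplification leaves the tracer channel flat", {
  sec <- noiseless_section(fold_r123 = c(1, 1))
  img <- sec$image
  expect_equal(mean(img$channels$r123[sec$lesion_mask > 0]),
               mean(img$channels$r123[sec$lesion_mask == 0]))
})

test_that("section generator flags bad vessel and lesion specifications", {
  lesions <- data.frame(lesion_id = c(1, 1), cr = c(20, 60), cc = c(20, 60),
                        radius_px = 10, fold_r123 = 1, fold_aib = 1)
  expect_error(generate_section(c(96, 96), lesions = lesions), "lesion ids")

  overlap <- data.frame(lesion_id = 1:2, cr = c(40, 44), cc = c(40, 44),
                        radius_px = 10, fold_r123 = 1, fold_aib = 1)
  expect_error(generate_section(c(96, 96), lesions = overlap), "overlap")

  tiny <- data.frame(vessel_id = 1, class = "bbb", r0 = 10, c0 = 10,
                     r1 = 20, c1 = 20, radius_px = 0.5, pgp_intensity = 20)
  expect_warning(out <- generate_section(c(64, 64), vessels = tiny),
                 "radius < 1")
  expect_true(all(out$vessel_mask == 0))
})

test_that("autoradiograph fold, dimensions and shift metadata are exact", {
  sec <- noiseless_section(fold_aib = c(4.9, 4.9))
  ar <- generate_autoradiograph(sec, downsample_factor = 1, noise_sd = 0)
  inside <- mean(ar$activity[sec$lesion_mask > 0])
  outside <- mean(ar$activity[sec$lesion_mask == 0])
  expect_equal(inside / outside, 4.9)

  ar4 <- generate_autoradiograph(sec, downsample_factor = 4)
  expect_equal(dim(ar4$activity), ceiling(dim(sec$lesion_mask) / 4))
  expect_equal(ar4$pixel_size, sec$image$pixel_size * 4)

  expect_error(generate_autoradiograph(sec, downsample_factor = 2.5),
               "integer")
})
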