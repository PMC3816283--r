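# Vessel segmentation and expression, lesion folds, co-registration,
# correlation.

test_that("segmentation recovers painted vessels pixel-for-pixel", {
  sec <- noiseless_section()
  mask <- segment_vessels(sec$image$channels$endothelial, min_size = 5)
  expect_equal(mask$n_vessels, 3L)
  expect_equal(mask$labels > 0, sec$vessel_mask > 0)
})

test_that("blank or constant channels yield empty masks, not errors", {
  blank <- matrix(0, 32, 32)
  m <- segment_vessels(blank)
  expect_equal(m$n_vessels, 0L)
  expect_equal(segment_vessels(matrix(7, 32, 32))$n_vessels, 0L)
})

test_that("undersized components are dropped and counted", {
  ch <- matrix(0, 32, 32)
  ch[5:6, 5:6] <- 100          # 4 px, below min_size 5
  ch[20:24, 20:24] <- 100      # 25 px, kept
  m <- segment_vessels(ch, min_size = 5)
  expect_equal(m$n_vessels, 1L)
  expect_equal(m$n_dropped, 1L)

  m2 <- segment_vessels(ch, min_size = 26)
  expect_equal(m2$n_vessels, 0L)
  expect_equal(m2$n_dropped, 2L)
})

test_that("labeling uses 8-connectivity", {
  ch <- matrix(0, 16, 16)
  for (i in 1:10) ch[i, i] <- 100  # pure diagonal line
  m <- segment_vessels(ch, min_size = 5)
  expect_equal(m$n_vessels, 1L)
})

test_that("per-vessel means equal configured intensities at zero noise", {
  sec <- noiseless_section(pgp = c(22.9, 22.6, 30))
  expr <- vessel_expression(sec$image$channels$pgp, sec$vessel_mask)
  expect_equal(expr$per_vessel$mean_intensity,
               sec$ground_truth$vessels$pgp_intensity)

  # constant channel: every vessel mean equals the constant
  const <- matrix(22.9, nrow(sec$vessel_mask), ncol(sec$vessel_mask))
  expr2 <- vessel_expression(const, sec$vessel_mask)
  expect_true(all(expr2$per_vessel$mean_intensity == 22.9))

  expect_error(vessel_expression(matrix(0, 4, 4), sec$vessel_mask), "shape")
})

test_that("vessel expression is invariant to label permutation", {
  sec <- noiseless_section()
  relabeled <- sec$vessel_mask
  relabeled[sec$vessel_mask == 1] <- 3L
  relabeled[sec$vessel_mask == 3] <- 1L
  a <- vessel_expression(sec$image$channels$pgp, sec$vessel_mask)$per_vessel
  b <- vessel_expression(sec$image$channels$pgp, relabeled)$per_vessel
  expect_equal(sort(a$mean_intensity), sort(b$mean_intensity))
  expect_equal(sort(a$n_pixels), sort(b$n_pixels))
})

test_that("class summaries report mean, SEM and n per vessel class", {
  sec <- noiseless_section()
  classes <- data.frame(vessel_id = 1:3, class = c("btb", "bbb", "bbb"))
  expr <- vessel_expression(sec$image$channels$pgp, sec$vessel_mask, classes)
  s <- expr$summary
  expect_equal(s$n[s$class == "bbb"], 2)
  expect_equal(s$mean[s$class == "btb"], 22.9)
  expect_equal(s$mean[s$class == "bbb"], mean(c(22.6, 30)))
})

test_that("lesion folds and areas equal generator ground truth exactly", {
  sec <- noiseless_section(fold_r123 = c(2, 5))
  bdt <- bdt_mask(sec$lesion_mask, margin_px = 10)
  out <- lesion_fold_change(sec$image$channels$r123, sec$lesion_mask, bdt,
                            sec$image$pixel_size)
  expect_equal(out$fold, c(2, 5))
  expect_equal(out$area_mm2, out$n_pixels * 2^2 * 1e-6)

  # constructed 4.9x ratio and folds {2, 5, 30}
  sec2 <- noiseless_section(fold_r123 = c(4.9, 30))
  out2 <- lesion_fold_change(sec2$image$channels$r123, sec2$lesion_mask,
                             bdt_mask(sec2$lesion_mask, 10), 2)
  expect_equal(out2$fold, c(4.9, 30))
})

test_that("fold change is invariant to global intensity scaling", {
  sec <- noiseless_section(fold_r123 = c(2, 5))
  bdt <- bdt_mask(sec$lesion_mask, 10)
  a <- lesion_fold_change(sec$image$channels$r123, sec$lesion_mask, bdt, 2)
  b <- lesion_fold_change(sec$image$channels$r123 * 37.5, sec$lesion_mask,
                          bdt, 2)
  expect_equal(a$fold, b$fold)
})

test_that("BDT mask excludes lesions plus margin and guards errors", {
  sec <- noiseless_section()
  bdt <- bdt_mask(sec$lesion_mask, margin_px = 8)
  expect_false(any(bdt & sec$lesion_mask > 0))
  # no pixel within 8 px of a lesion
  near <- as.matrix(EBImage::distmap(EBImage::Image(sec$lesion_mask == 0))) < 8
  expect_false(any(bdt & near & sec$lesion_mask == 0))
  # without lesions everything is reference tissue
  expect_true(all(bdt_mask(matrix(0L, 8, 8))))

  expect_error(lesion_fold_change(sec$image$channels$r123, sec$lesion_mask,
                                  sec$lesion_mask > 0, 2), "overlaps")
  expect_error(lesion_fold_change(sec$image$channels$r123, sec$lesion_mask,
                                  matrix(FALSE, 96, 96), 2), "empty")
})

test_that("registration of identical images returns zero shift", {
  sec <- noiseless_section()
  ref <- sec$image$channels$nuclei
  reg <- register_modalities(ref, ref, max_shift = 5)
  expect_equal(unname(reg$shift), c(0, 0))
  expect_equal(reg$correlation, 1)
})

test_that("registration recovers injected shifts exactly", {
  sec <- noiseless_section()
  for (s in list(c(3L, -2L), c(-5L, 4L), c(0L, 6L))) {
    ar <- generate_autoradiograph(sec, downsample_factor = 1, shift_px = s)
    reg <- register_modalities(sec$image$channels$nuclei, ar, max_shift = 8)
    expect_equal(unname(reg$shift), s)
  }
})

test_that("flat and uncorrelated inputs are diagnosed", {
  expect_error(register_modalities(matrix(1, 20, 20), matrix(rnorm(400), 20)),
               "flat")
  set.seed(8)
  expect_warning(
    reg <- register_modalities(matrix(rnorm(4900), 70),
                               matrix(rnorm(4900), 70), max_shift = 3),
    "low registration correlation")
  expect_lt(reg$correlation, 0.2)
})

test_that("correlate returns r^2 and the OLS slope", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r_squared, 1)
  expect_equal(correlate(x, 2 * x + 1)$slope, 2)

  hand <- correlate(c(0, 1, 2), c(0, 1, 0))
  expect_equal(hand$r_squared, 0)
  expect_equal(hand$slope, 0)

  expect_error(correlate(1:2, 1:2), "length")
  expect_error(correlate(rep(1, 5), 1:5), "variance")

  # null case: E[r^2] ~ 1/(n-1)
  set.seed(12)
  r2 <- replicate(300, correlate(rnorm(1000), rnorm(1000))$r_squared)
  expect_equal(mean(r2), 1 / 999, tolerance = 0.25)
})
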