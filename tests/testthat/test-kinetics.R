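# Transfer-constant estimation: multipoint line, single-time-point
# correction, vascular volume, inhibitor folds.

noiseless_records <- function(kin_ul = 0.12, v0 = 0.015, cstar = 50,
                              times = c(30, 60, 90, 120)) {
  generate_perfusion_series(kin_ul, v0, cstar, times, noise_cv = 0,
                            n_per_time = 1, seed = 1)
}

test_that("multipoint fit is exact on noiseless uptake points", {
  fit <- fit_kin(noiseless_records())
  expect_equal(fit$kin, 0.12)
  expect_equal(fit$v0, 0.015)
  expect_equal(fit$kin_se, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)), c(0.12, 0.015))
  expect_equal(predict(fit, 120), 0.0294)
})

test_that("impermeant tracer fits slope 0 with intercept V0", {
  fit <- fit_kin(noiseless_records(kin_ul = 0))
  expect_equal(fit$kin, 0)
  expect_equal(fit$v0, 0.015)
})

test_that("single distinct time is redirected to the single-point method", {
  rec <- noiseless_records(times = 120)
  expect_error(fit_kin(rec), "single_timepoint")
})

test_that("noisy multipoint estimates agree with the normal-equations oracle", {
  rec <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0.1,
                                   n_per_time = 5, seed = 23)
  fit <- fit_kin(rec)
  o <- ols_oracle(rec$time_s, rec$qstar_ug_per_g / rec$cstar_ug_per_ml)
  expect_equal(fit$kin, o$slope * 1000)
  expect_equal(fit$kin_se, o$slope_se * 1000)
  expect_equal(fit$v0, o$intercept)
  expect_lt(abs(fit$kin - 0.12), 3 * fit$kin_se)
})

test_that("single-time-point K_in evaluates the vascular correction", {
  fit <- kin_single_timepoint(1.47, 50, 120, 0.015)
  expect_equal(fit$kin, 0.12)
  expect_equal(fit$n, 1L)
  expect_equal(fit$kin_se, 0)

  # pure vascular signal
  expect_equal(kin_single_timepoint(0.015 * 50, 50, 120, 0.015)$kin, 0)

  expect_error(kin_single_timepoint(0.75, 50, 0, 0.015), "time_s")
  expect_error(kin_single_timepoint(0.75, 0, 120, 0.015), "cstar")
})

test_that("replicates aggregate per record as mean with SEM", {
  q <- c(1.40, 1.47, 1.54)
  fit <- kin_single_timepoint(q, 50, 120, 0.015)
  per <- (q - 0.015 * 50) / (50 * 120) * 1000
  expect_equal(fit$kin, mean(per))
  expect_equal(fit$kin_se, sd(per) / sqrt(3))
  expect_equal(fit$per_record_kin, per)
})

test_that("tissue signal below the vascular component is flagged", {
  expect_warning(fit <- kin_single_timepoint(0.5, 50, 120, 0.015),
                 "negative")
  expect_lt(fit$kin, 0)
  expect_equal(fit$flagged_negative, 1L)
})

test_that("vascular volume is the mean distribution volume with SEM", {
  rec <- data.frame(qstar_ug_per_g = c(0.13, 0.15, 0.17),
                    cstar_ug_per_ml = 10, time_s = 60)
  v <- vascular_volume(rec)
  expect_equal(v$v0, 0.015)
  expect_equal(v$v0_se, sd(c(0.013, 0.015, 0.017)) / sqrt(3))
  expect_equal(v$v0_se, 0.00115, tolerance = 5e-3)

  one <- vascular_volume(rec[1, ])
  expect_equal(one$v0_se, 0)
  expect_error(vascular_volume(rec[0, ]), "no impermeant")

  # generator identity: impermeant tracer recovers configured V0 at noise 0
  suc <- generate_perfusion_series(0, 0.015, 10, noise_cv = 0, seed = 2)
  expect_equal(vascular_volume(suc)$v0, 0.015)
})

test_that("inhibitor folds are ratios of transfer constants", {
  expect_equal(inhibitor_fold(2.4, 0.12), 20)
  expect_equal(inhibitor_fold(2.2, 0.12), 2.2 / 0.12)
  expect_equal(inhibitor_fold(0.37, 0.37), 1)
  expect_error(inhibitor_fold(1, 0), "baseline")
})

test_that("single-point method reproduces the multipoint slope on the line", {
  # consistency: Eq on any noiseless point with the true V0 equals the slope
  rec <- noiseless_records()
  fit <- fit_kin(rec)
  for (i in seq_len(nrow(rec))) {
    expect_equal(
      kin_single_timepoint(rec$qstar_ug_per_g[i], rec$cstar_ug_per_ml[i],
                           rec$time_s[i], 0.015)$kin,
      fit$kin)
  }
})

test_that("K_in is invariant under consistent unit rescaling", {
  rec <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0.1,
                                   n_per_time = 3, seed = 9)
  fit <- fit_kin(rec)
  # express tracer amounts in ng/g and ng/mL instead of ug
  rec2 <- rec
  rec2$qstar_ug_per_g <- rec$qstar_ug_per_g * 1000
  rec2$cstar_ug_per_ml <- rec$cstar_ug_per_ml * 1000
  expect_equal(fit_kin(rec2)$kin, fit$kin)
})

test_that("mixed experimental groups are refused", {
  rec <- rbind(
    generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0, seed = 1),
    generate_perfusion_series(2.4, 0.015, 50, noise_cv = 0,
                              inhibitor = "cyclosporinA", seed = 1))
  expect_error(fit_kin(rec), "inhibitor")
})

test_that("simulated experiments recover K_in without bias (small batch)", {
  # small-scale parameter-recovery check; the full calibration runs in the
  # acceptance suite
  ests <- ses <- numeric(50)
  for (i in 1:50) {
    rec <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0.1,
                                     n_per_time = 5, seed = 1000 + i)
    f <- fit_kin(rec)
    ests[i] <- f$kin
    ses[i] <- f$kin_se
  }
  expect_lt(abs(mean(ests) - 0.12), 3 * sd(ests) / sqrt(50))
  cover <- mean(abs(ests - 0.12) <= 2 * ses)
  expect_gt(cover, 0.85)
})
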