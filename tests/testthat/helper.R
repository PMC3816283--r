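# Shared test fixtures and independent oracles.

# Independent OLS oracle from the normal equations: slope, intercept and
# their standard errors computed in closed form, no lm() involved.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(
    slope = slope, intercept = intercept,
    slope_se = sqrt(s2 / sxx),
    intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  )
}

# A small noiseless section: two lesions, three hand-placed vessels.
noiseless_section <- function(shape = c(96, 96), fold_r123 = c(2, 5),
                              fold_aib = c(4.9, 3), pgp = c(22.9, 22.6, 30),
                              blur_sigma = 0, noise_sd = 0) {
  lesions <- data.frame(
    lesion_id = 1:2, cr = c(28, 68), cc = c(30, 64),
    radius_px = c(12, 14), fold_r123 = fold_r123, fold_aib = fold_aib
  )
  vessels <- data.frame(
    vessel_id = 1:3, class = c("btb", "bbb", "bbb"),
    r0 = c(26, 10, 80), c0 = c(26, 70, 14),
    r1 = c(32, 18, 88), c1 = c(32, 78, 16),
    radius_px = c(2, 2.5, 2), pgp_intensity = pgp
  )
  generate_section(shape, pixel_size = 2, vessels = vessels,
                   lesions = lesions, blur_sigma = blur_sigma,
                   noise_sd = noise_sd, seed = 7)
}
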