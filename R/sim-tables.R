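# Synthetic tabular inputs: fluorescence standards and perfusion records.

#' Simulate brain-homogenate fluorescence standards
#'
#' Emulates a dilution series of dye spiked into brain homogenate, sectioned
#' and imaged: the sum fluorescence intensity per gram of analyzed tissue is
#' linear in the dye concentration, with additive Gaussian noise on the
#' intensity-per-gram scale (camera read noise).
#'
#' @param concentrations dye concentrations in ug dye per g tissue (>= 0).
#' @param slope true intensity-per-gram gain per (ug/g) of dye.
#' @param intercept background intensity per gram (tissue autofluorescence).
#' @param noise_sd additive noise SD on the intensity-per-gram scale (>= 0).
#' @param n_replicates replicate sections per concentration (>= 1).
#' @param mass_g analyzed tissue mass per section in grams; the default is
#'   the mass of a 1e8 um^2 region of a 20 um section at 1.04 g/cm^3.
#' @param seed integer seed; identical seed and parameters give identical
#'   tables.
#' @return data.frame with columns `conc_ug_per_g`, `sum_intensity`, `mass_g`.
#' @examples
#' std <- generate_standards(c(0, 1, 2, 5), slope = 100, intercept = 50,
#'                           noise_sd = 0, n_replicates = 1, seed = 1)
#' std$sum_intensity / std$mass_g  # exactly 100 * conc + 50
#' @export
generate_standards <- function(concentrations, slope = 100, intercept = 50,
                               noise_sd = 5, n_replicates = 3,
                               mass_g = region_mass(1e8), seed = 1) {
  check_positive(concentrations, "concentrations", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  check_positive(mass_g, "mass_g")
  conc <- rep(concentrations, each = n_replicates)
  ipg <- with_seed(substream_seed(seed, "standards"), {
    slope * conc + intercept + stats::rnorm(length(conc), 0, noise_sd)
  })
  data.frame(
    conc_ug_per_g = conc,
    sum_intensity = ipg * mass_g,
    mass_g = mass_g
  )
}

#' Simulate timed-perfusion uptake records
#'
#' Draws tissue tracer quantities from the linear single-time uptake model
#' `Q*/C* = K_in * T + V0` within the linear-uptake window, with
#' multiplicative Gaussian noise on Q* (coefficient of variation
#' `noise_cv`), mimicking inter-animal variability.
#'
#' @param true_kin true transfer constant in uL/s/g (>= 0).
#' @param v0 true vascular volume in mL/g (> 0).
#' @param cstar perfusate tracer concentration C* in ug/mL (> 0).
#' @param times perfusion durations in seconds; the default 30-120 s is the
#'   window over which uptake is linear.
#' @param noise_cv coefficient of variation of the multiplicative noise on
#'   Q* (>= 0).
#' @param n_per_time independent animals per time point (>= 1).
#' @param tracer,region,inhibitor labels copied onto every record.
#' @param seed integer seed.
#' @return data.frame of perfusion records with columns `tracer`, `region`,
#'   `inhibitor`, `qstar_ug_per_g`, `cstar_ug_per_ml`, `time_s`.
#' @examples
#' # noiseless: Q* = 50 * (1.2e-4 * 120 + 0.015) = 1.47 ug/g
#' generate_perfusion_series(0.12, 0.015, 50, times = 120, noise_cv = 0,
#'                           n_per_time = 1, seed = 1)$qstar_ug_per_g
#' @export
generate_perfusion_series <- function(true_kin, v0, cstar,
                                      times = c(30, 60, 90, 120),
                                      noise_cv = 0.1, n_per_time = 5,
                                      tracer = "R123", region = "normal",
                                      inhibitor = "none", seed = 1) {
  check_positive(true_kin, "true_kin", strict = FALSE)
  check_positive(v0, "v0")
  check_positive(cstar, "cstar")
  check_positive(times, "times")
  check_positive(noise_cv, "noise_cv", strict = FALSE)
  if (n_per_time < 1) stop("`n_per_time` must be >= 1", call. = FALSE)
  tt <- rep(times, each = n_per_time)
  q0 <- cstar * (true_kin / 1000 * tt + v0) # uL/s/g -> mL/s/g
  stream <- paste("perfusion", tracer, region, inhibitor, sep = "/")
  q <- with_seed(substream_seed(seed, stream), {
    q0 * (1 + stats::rnorm(length(q0), 0, noise_cv))
  })
  data.frame(
    tracer = tracer, region = region, inhibitor = inhibitor,
    qstar_ug_per_g = q, cstar_ug_per_ml = cstar, time_s = tt
  )
}
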