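# Fluorescence-to-concentration calibration via brain-homogenate standards.

#' Fit a fluorescence standard curve on brain-homogenate standards
#'
#' Ordinary least-squares line of sum intensity per gram of tissue on dye
#' concentration. The intercept is retained by default: homogenate
#' autofluorescence and any non-dark-subtracted camera offset show up as an
#' intensity-per-gram background, which the intercept absorbs. Set
#' `through_origin = TRUE` to force the line through zero.
#'
#' @param standards data.frame with columns `conc_ug_per_g`, `sum_intensity`,
#'   `mass_g` (as produced by [generate_standards()]), or columns
#'   `conc_ug_per_g` and `intensity_per_g`.
#' @param through_origin logical; drop the intercept.
#' @return object of class `standard_curve` with fields `slope` (intensity
#'   per ug/g), `intercept` (intensity-per-gram background), `r_squared`,
#'   `n_points`, and the underlying `lm` fit.
#' @examples
#' std <- generate_standards(c(0, 1, 2, 5), slope = 100, intercept = 50,
#'                           noise_sd = 0, n_replicates = 2, seed = 1)
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, through_origin = FALSE) {
  if (!"conc_ug_per_g" %in% names(standards)) {
    stop("`standards` must have a `conc_ug_per_g` column", call. = FALSE)
  }
  ipg <- if ("intensity_per_g" %in% names(standards)) {
    standards$intensity_per_g
  } else {
    check_positive(standards$mass_g, "mass_g")
    standards$sum_intensity / standards$mass_g
  }
  conc <- standards$conc_ug_per_g
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct standard concentrations", call. = FALSE)
  }
  if (stats::var(conc) == 0) {
    stop("standard concentrations have zero variance", call. = FALSE)
  }
  d <- data.frame(conc = conc, ipg = ipg)
  fit <- if (through_origin) stats::lm(ipg ~ conc - 1, data = d)
         else stats::lm(ipg ~ conc, data = d)
  cf <- stats::coef(fit)
  structure(
    list(
      slope = unname(if (through_origin) cf["conc"] else cf["conc"]),
      intercept = if (through_origin) 0 else unname(cf["(Intercept)"]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = nrow(d),
      through_origin = through_origin,
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Fluorescence standard curve (intensity/g vs ug dye/g)\n")
  cat(sprintf("  slope: %.6g  intercept: %.6g  r^2: %.4f  n: %d\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
summary.standard_curve <- function(object, ...) summary(object$fit, ...)

#' Predicted intensity per gram at given dye concentrations
#' @param object a `standard_curve`.
#' @param concentration dye concentrations in ug/g.
#' @param ... unused.
#' @export
predict.standard_curve <- function(object, concentration, ...) {
  object$slope * concentration + object$intercept
}

#' Mass of an imaged tissue region from its area
#'
#' Converts an analyzed region's area to tissue mass: area (um^2) times
#' section thickness (um) gives the analyzed volume in um^3, converted to
#' cm^3 (x 1e-12) and multiplied by the tissue density.
#'
#' @param area_um2 region area in um^2 (>= 0).
#' @param thickness_um section thickness in um (default 20).
#' @param density_g_cm3 tissue density in g/cm^3 (default 1.04, brain).
#' @return mass in grams.
#' @examples
#' region_mass(1e8)  # 2.08e-3 g
#' @export
region_mass <- function(area_um2, thickness_um = 20, density_g_cm3 = 1.04) {
  check_positive(area_um2, "area_um2", strict = FALSE)
  check_positive(thickness_um, "thickness_um")
  check_positive(density_g_cm3, "density_g_cm3")
  area_um2 * thickness_um * 1e-12 * density_g_cm3
}

#' Convert sum fluorescence intensity to tissue dye concentration
#'
#' Inverts the standard curve: concentration (ug dye / g tissue) =
#' `((sum_intensity / mass) - intercept) / slope`. Back-calculated
#' concentrations below zero (regions dimmer than the homogenate
#' background) are returned as-is, not clamped, so that population means
#' stay unbiased; their positions are flagged in the `"flagged_negative"`
#' attribute and a warning is raised.
#'
#' @param sum_intensity summed pixel intensity of the region (a.u.).
#' @param mass_g analyzed region mass in grams (> 0), e.g. [region_mass()].
#' @param curve a [fit_standard_curve()] object with `slope > 0`.
#' @return concentrations in ug/g with attribute `flagged_negative`.
#' @examples
#' std <- generate_standards(c(0, 1, 2, 5), noise_sd = 0, seed = 1)
#' cur <- fit_standard_curve(std)
#' intensity_to_concentration(250 * 2.08e-3, 2.08e-3, cur)  # 2 ug/g
#' @export
intensity_to_concentration <- function(sum_intensity, mass_g, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  check_positive(mass_g, "mass_g")
  if (curve$slope <= 0) {
    stop("standard curve slope must be > 0", call. = FALSE)
  }
  conc <- ((sum_intensity / mass_g) - curve$intercept) / curve$slope
  # tolerance keeps float-zero round-trips from being flagged
  neg <- conc < -1e-9
  if (any(neg)) {
    warning(sprintf("%d back-calculated concentration(s) below zero; %s",
                    sum(neg), "returned unclamped and flagged"))
  }
  attr(conc, "flagged_negative") <- which(neg)
  conc
}
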