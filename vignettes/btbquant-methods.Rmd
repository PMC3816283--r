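---
title: "Methods: dual-tracer quantification of BBB and BTB permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tracer quantification of BBB and BTB permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btbquant)
```

## The experiment this package models

A small-molecule tracer is perfused through the cerebral circulation at a
known concentration $C^*$ (µg/mL) for a controlled time $T$ (seconds). At
the end of the perfusion the brain is sectioned and the tracer quantity in
tissue $Q^*$ (µg/g) is measured — by quantitative fluorescence microscopy
for a fluorescent probe such as rhodamine 123 (R123), or by quantitative
autoradiography for a radiolabeled passive marker such as
$^{14}$C-aminoisobutyric acid (AIB). Because both modalities can be read
from the *same* section, the passive leakiness of a metastatic lesion's
vasculature (the blood–tumor barrier, BTB) and the residual activity of
efflux transporters such as P-glycoprotein (P-gp) can be measured
simultaneously, lesion by lesion.

`btbquant` implements the complete analysis chain for such an experiment,
plus a synthetic-data generator that produces every input with recorded
ground truth so the chain is testable end to end without animal data.

## Uptake kinetics

Over the early, linear portion of the uptake curve the tissue distribution
volume obeys

$$\frac{Q^*}{C^*} = K_{in} \, T + V_0,$$

where $K_{in}$ (mL/s/g, reported in µL/s/g) is the unidirectional
blood-to-brain transfer constant and $V_0$ (mL/g) is the $T = 0$ intercept —
the vascular volume occupied by tracer that never left the blood.
`fit_kin()` estimates both by unweighted ordinary least squares of
$Q^*/C^*$ on $T$ and returns a classed fit with `print`, `coef`,
`predict`, `confint` and `plot` methods. Linearity over the perfusion
window is an assumption of the model, not something the fit detects; the
fit's $r^2$ is reported as a diagnostic.

When a single perfusion time inside the linear window is used,
`kin_single_timepoint()` applies the closed-form correction

$$K_{in} = \frac{Q^* - V_0 C^*}{C^* \, T},$$

with $V_0$ supplied externally — in practice from a parallel perfusion of
an impermeant tracer (sucrose), whose distribution volume
`vascular_volume()` averages across animals. Replicates are aggregated by
computing $K_{in}$ per record and reporting mean ± SEM, matching
per-animal reporting conventions; pooling $Q^*$ first would weight animals
unequally. Negative estimates (tissue signal below the vascular component)
are returned unclamped but flagged, so group means stay unbiased.

$V_0$ precedence, when several sources are available, is: an explicit
argument, then an impermeant-tracer estimate from the same batch, then the
multipoint intercept; each fit records which source it used
(`v0_source`).

## Fluorescence calibration

Microscope sum intensity is converted to µg dye per g tissue through
brain-homogenate standards: known dye concentrations are homogenized into
brain, sectioned and imaged like the experimental tissue, and
`fit_standard_curve()` fits intensity-per-gram against concentration by
OLS. The intercept is retained by default — homogenate autofluorescence
and any non-dark-subtracted camera offset appear as an intensity-per-gram
background, and the intercept absorbs both (a `through_origin` switch is
provided). The analyzed mass comes from geometry:
`region_mass(area_um2, thickness_um, density_g_cm3)` converts region area
× section thickness (default 20 µm) × brain density (default
1.04 g/cm³) to grams. `intensity_to_concentration()` then inverts the
line. The fit is unweighted; no variance model is imposed on the
standards.

## Efflux profiling

Compounds that enter brain passively show a linear relationship between
LogD (octanol/water distribution coefficient at pH 7.4) and
$\log_{10} K_{in}$ (in mL/s/g, hence `log_kin()` divides µL/s/g values by
1000). `fit_passive_line()` fits that line on reference passive
compounds; `efflux_deviation()` measures how far below the line a test
compound falls (deviation = predicted − observed, positive below) and
flags efflux suspects at a threshold of 1.0 log unit by default. The
threshold sits well above typical passive scatter about the line
(residual SD well under half a log unit in the packaged reference set)
while being far below the ~3 log-unit deviation of a strongly effluxed
probe, so the flag is robust to the exact reference set. The packaged
compound table (`load_reference_compounds()`) is *synthetic
configuration*: LogD values are literature-typical, but the transfer
constants were constructed around a representative line
($\log_{10} K_{in} = 0.45\,\mathrm{LogD} - 1.60$); users with measured
reference data should supply their own CSV.

## Imaging quantification

Vessels are segmented from the endothelial-marker channel by Otsu
thresholding followed by 8-connected component labeling (implemented
in-package; diagonal connectivity matters for thin, angled tubes), with
components under `min_size` (default 10 px) dropped and counted.
`vessel_expression()` averages the transporter channel over each vessel
region and summarizes per class (BBB vs BTB) as mean ± SEM of per-vessel
means. Pixels are treated as point samples at pixel centers; masks are
label images; areas are pixel counts × pixel area, with no sub-pixel
boundary handling.

Lesion tracer accumulation is expressed as a fold change over "brain
distant to tumor" (BDT): `lesion_fold_change()` divides each lesion's mean
signal by the mean over the BDT mask, which `bdt_mask()` defines as all
non-lesion pixels at least `margin_px` (default 50 px) from any lesion
pixel. Fold changes are ratio-scale: multiplying an image by a positive
constant leaves them unchanged, so they are insensitive to exposure and
gain. Lesion masks come from the generator's ground truth in the packaged
workflows; threshold-based lesion detection on real data is possible but
the quantitative contract is defined on known masks.

Autoradiograph-to-section registration (`register_modalities()`) searches
integer translations within ±`max_shift` pixels for the maximum Pearson
correlation over the overlap, after pixel-replication upsampling of the
coarse activity image. Same-slice modalities share orientation and scale,
so rotation and scaling are deliberately not searched. Known displacements
are injected by the generator in section-grid pixels *before*
downsampling, so exact recovery is guaranteed when the displacement is a
multiple of the downsample factor (including factor 1, which the tests
use); sub-block displacements are recovered only to the nearest block.
A flat image is an error, and a best correlation under 0.2 raises a
warning rather than a silent bad alignment.

## Statistics

`two_sample_t()` is the classic two-sided Student t-test
(pooled-variance by default, matching the field's convention; Welch by
flag). `anova_dunnett()` fits a one-way ANOVA and performs Dunnett's
many-to-one comparisons against the control with pooled-variance t
statistics. The family-wise critical value is obtained by seeded
Monte-Carlo simulation of the null maximum-|t| distribution (default
$10^5$ draws) rather than from tables: this is exact to Monte-Carlo error
for any number of groups and unequal group sizes, and collapses to the
pooled-t quantile when there is a single treatment. Adjusted p-values are
Monte-Carlo tail probabilities of max |t|. All p-values are two-sided.

## What the generator emulates — and what it does not

`simulate_study()` draws every input from one top-level seed through
named substreams (one per artifact), so identical seed + configuration
gives byte-identical outputs and adding an artifact never perturbs the
others. Its defaults are the study conditions of the perfusion experiment
it emulates: $C^* = 50$ µg/mL over 30–120 s; baseline
$K_{in} = 0.12$ µL/s/g over $V_0 = 0.015$ mL/g; transporter inhibition
raising $K_{in}$ to 2.4 (cyclosporin A) and 2.2 (verapamil) µL/s/g;
n = 4 animals per group (reported group sizes ranged 3–5; 4 is the
midpoint); multiplicative noise on $Q^*$ with CV 0.1 (inter-animal
variability); additive Gaussian noise on images (camera read noise);
per-vessel transporter intensities of 22.6 (BBB) and 22.9 (BTB) a.u.;
lesions amplifying the passive tracer 4.9-fold and the efflux substrate
0.98-fold over BDT.

The per-vessel intensity SD defaults to 10 a.u.: reported SEMs of
0.4 (n = 756) and 0.3 (n = 1214) imply population SDs of about 11 and
10.5, and 10 is the round value consistent with both.

The imaging problem sizes are scaled for fast, exhaustive testing: a
224 × 224 px section at 2 µm/px with 4 lesions (radius 14–22 px) and
20 BBB + 12 BTB vessels — preserving the ~0.6 BTB:BBB vessel-count ratio
of whole-slide data rather than its thousands of vessels — and the BDT
margin is 24 px in the packaged study configuration (the `bdt_mask()`
default of 50 px suits whole-slide fields). Vessels are straight,
constant-intensity tubes placed without overlap so per-vessel ground
truth is exact; no vessel-geometry statistics were available to match, so
count and radius ranges are configuration with these documented defaults.

Deliberately *not* modeled: realistic histology texture, vascular network
topology (branching, tortuosity), photon/shot-noise camera physics,
partial-volume effects at lesion boundaries, and non-rigid deformation
between modalities. Passing tests therefore demonstrate correctness of
the estimators and measurement operators under the stated noise models —
not robustness to every artifact of real microscopy.

## Numerical choices and degenerate inputs

- Zero-noise conservation is exact by construction: blur and noise are
  applied last, so with both at zero every region statistic equals its
  configured value, and the generator's uptake model is the same model the
  kinetics module fits (no model mismatch at noise 0).
- Standard-curve and passive-line fits refuse fewer than 3 distinct
  concentrations / 2 distinct LogD values; a single perfusion time is an
  error that points to the single-time-point estimator.
- Back-calculated concentrations below zero are flagged at a −10⁻⁹
  tolerance so exact round-trips of zero-concentration standards are not
  spuriously flagged.
- Otsu thresholding of a constant channel returns an empty mask (0
  vessels) rather than erroring; a vessel radius below 1 px is skipped
  with a warning; overlapping lesions are an error.
- Registration ties (identical correlation at several shifts) resolve to
  the first maximum in row-major order; in practice noiseless landmarks
  make the maximum unique.
- TIFF channels are stored scaled into [0, 1] with the scale in the JSON
  sidecar (32-bit float frames); file round-trips are exact to ~10⁻⁹
  relative, so equality contracts are defined on in-memory objects.

## Known limitations

- One-compartment influx only: no efflux rate constant ($k_{out}$),
  capillary heterogeneity, or protein-binding correction.
- Linearity of uptake over the perfusion window is assumed, not tested.
- Registration is integer-translation only, by design.
- The efflux screen attributes deviation to "efflux" generically; it
  cannot distinguish P-gp from BCRP or MRP transport.
- Lesion "size" is per-slice mask area (mm²), not a largest-cross-section
  or volumetric measure.
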