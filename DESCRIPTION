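Package: btbquant
Title: Quantitative Dual-Tracer Analysis of Blood-Brain and Blood-Tumor
    Barrier Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of blood-brain barrier (BBB) and
    blood-tumor barrier (BTB) tracer kinetics from in-situ perfusion and
    same-slice dual-modality imaging. Fits fluorescence standard curves on
    brain-homogenate standards and converts sum intensity to tissue dye
    concentration; estimates unidirectional blood-to-brain transfer
    constants (K_in) with vascular-volume (V0) correction from timed
    perfusion records; classifies efflux-transporter substrates by their
    deviation from the passive LogD-LogK_in relationship; quantifies
    per-vessel transporter expression within endothelial-marker-defined
    regions; co-registers fluorescence sections with coarse autoradiographs
    and measures per-lesion fold changes; and performs the associated group
    comparisons (Student t-test, one-way ANOVA with Monte-Carlo Dunnett
    many-to-one contrasts). A synthetic-data module generates every input
    with recorded ground truth so the full pipeline is testable without
    animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
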