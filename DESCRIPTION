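Package: ergoct
Title: Scotopic ERG Decomposition and Retinal OCT Sector Analysis for
    Preclinical Drug Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vivo retinal biomarkers in longitudinal
    pharmacology studies. Decomposes dark-adapted full-field flash
    electroretinogram (ERG) waveforms into the photoreceptoral P3 component
    (delayed-Gaussian phototransduction model, yielding the saturated
    amplitude RmP3) and the ON-bipolar-cell P2 component (zero-phase
    frequency-domain low-pass at 46.9 Hz after P3 subtraction), computes
    ETDRS outer-ring quadrant means from segmented optical coherence
    tomography (OCT) layer-thickness maps, and provides the longitudinal
    statistical layer used for drug-effect screening: baseline
    normalisation, ROUT robust outlier detection, two-way repeated-measures
    ANOVA with separate error strata, and Sidak-adjusted post hoc
    comparisons at specific times. A seeded synthetic-cohort generator with
    known ground truth makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
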