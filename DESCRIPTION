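Package: fundusgeom
Title: Retinal Vessel Morphometry, Optic Nerve Subarachnoid Space, and
    Case-Control Statistics for Retinal Vein Occlusion Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the geometry of the retinal vasculature from fundus
    photographs: vessel segmentation with a multiscale vesselness baseline,
    artery/vein discrimination, optic disc segmentation by polar edge
    extraction with the disc diameter (DD) defined by the smallest
    circumscribed circle, centerline extraction by topology-preserving
    thinning, per-point vessel diameters, relative arteriolar and venular
    calibers in the 1.0-1.5 DD annulus, the arteriolar-to-venular ratio
    (AVR), and bifurcation branching angles by retinal quadrant.  Includes
    calculators for the optic nerve subarachnoid space width (ONSASW) and
    the trans-lamina cribrosa pressure difference (TLCPD) from tabular MRI
    measurements, a synthetic fundus-image and cohort simulator with exact
    geometric ground truth for validation, and a case-control statistical
    workflow (normality/variance gating, paired and independent two-sample
    tests, chi-square, one-way ANOVA, multivariable logistic regression
    with adjusted odds ratios) producing demographic and per-eye
    comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    car,
    nortest
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
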