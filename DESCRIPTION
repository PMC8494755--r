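Package: ffaleak
Title: Quantification of Retinal Blood Leakage in Fundus Fluorescein Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating and quantifying diffuse blood-leakage regions
    from blood vessels in time series of fundus fluorescein angiography (FFA)
    frames. Small vessels are removed by oriented grayscale openings and large
    vessels by perpendicular-opening residues followed by log-Gabor quadrature
    vessel enhancement, hysteresis thresholding and Chan-Vese segmentation. A
    vessel-convergence reference point is detected by skeleton-graph line
    voting and used to initialize rigid intensity-based registration of every
    frame to the first timepoint. Registered leakage images are summarized as
    relative-intensity, leakage-area and in-region-intensity time series, with
    evaluation utilities for comparing against reference annotations. A seeded
    synthetic phantom generator with full ground truth supports testing and
    method validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    png,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
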