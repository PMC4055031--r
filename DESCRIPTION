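Package: rotalign
Title: Rotation Prealignment for 2D Image Registration by Orientation
    Histogram Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the rotational difference between mono- and
    multimodality 2D medical images by matching gradient-magnitude-weighted
    orientation histograms cyclically under L1 or L2 cost, without feature
    extraction or segmentation. Includes Gaussian-derivative gradient fields
    with non-maximal suppression, inscribed-circle histogram accumulation,
    sub-bin refinement and 180-degree ambiguity detection, phase-correlation
    translation estimation, an edge-map (Canny / Fourier-polar / phase
    correlation) baseline estimator, iterative affine SSD registration with
    optional rotation prealignment, and a synthetic phantom generator for
    benchmarking against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    digest,
    png,
    tiff,
    RNifti,
    tibble,
    ggplot2,
    rlang,
    generics,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
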