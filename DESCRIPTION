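Package: spinemorph
Title: Synthetic STED Spine Imaging, Morphometry and Compartmentalization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates STED-like fluorescence image stacks of GFP-filled
    dendrites bearing spines, measures spine morphology on them
    (curvature-following spine length, Gaussian-fit FWHM neck and head
    widths, spine density), computes the diffusional compartmentalization
    factor V*L/A of each spine together with its recovery-time-constant
    interpretation, and provides the accompanying two-group statistical
    workflow (normality-gated t / Mann-Whitney tests, two-sample
    Kolmogorov-Smirnov against a reference group) plus scalar indices for
    synaptic physiology and behaviour (LTP magnitude, paired-pulse ratio,
    NMDAR/AMPAR ratio, tonic current shift, displacement index, novel-arm
    fraction, specific radioligand binding). All functions take and return
    tidy data frames so a full synthetic experiment chains with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
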