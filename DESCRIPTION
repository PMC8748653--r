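Package: flimfish
Title: Combinatorial Spectral and Lifetime Phasor Decoding for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial transcriptomics experiments that encode mRNA
    targets with combinatorial pairs of fluorophores distinguished jointly by
    emission spectrum and fluorescence lifetime. Implements fit-free lifetime
    and spectral phasor transforms of time-resolved multichannel image stacks,
    a synthetic-data generator with ground truth, 3D detection of
    diffraction-limited puncta, Gaussian-mixture classification of puncta in
    4D phasor space with explicit error rejection (undetermined and
    overlapping events), nucleus-seeded tessellation of the imaged volume into
    cell territories with per-cell counting, and an analytic model of optical
    crowding with Monte-Carlo verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
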