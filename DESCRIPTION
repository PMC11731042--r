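Package: scnphase
Title: Spatiotemporal Circadian Phase Mapping for SCN Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatiotemporal analysis of circadian rhythms in
    suprachiasmatic nucleus (SCN) slice imaging: preprocessing of registered
    bioluminescence and fluorescence movie stacks, region-of-interest and
    single-cell time-series extraction, FFT-NLLS rhythm fitting with relative
    amplitude error, empirical JTK_CYCLE-style rhythmicity testing with
    asymmetry search, Lloyd k-means phase clustering with inter-cluster phase
    dispersal (circular variance), phase-wave direction vectors, circular
    statistics (Rayleigh test, wrapped kernel densities), and single-cell
    phase-dispersion summaries. Includes a synthetic SCN movie generator with
    planted ground truth so every stage of the pipeline can be validated
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
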