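Package: tempodiff
Title: Multi-Metric Divergence Screening for Two-Condition Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks genes by how strongly their expression trajectory diverges
    between two conditions (for example wild type versus knockout) across a
    short time course. Raw counts are normalized to log2(TPM+1), low-variance
    genes are removed, each gene's two series are minmax-scaled jointly, and
    twelve time-series dissimilarity measures (Euclidean, short-time-series,
    dynamic time warping, time-alignment measurement, autocorrelation,
    Fourier, compression-based, complexity-invariant, correlation,
    periodogram, integrated periodogram, and discrete Frechet) are computed
    per gene. Genes are selected per metric by an empirical tail probability
    over the observed distances and ranked by cross-metric consensus. A
    synthetic two-condition time-course generator with ground-truth labels
    supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
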