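Package: trunknav
Title: View-Based Navigation of Ants Descending Tree Trunks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how tree-dwelling ants can use panoramic
    view matching to position themselves toward the nest while descending a
    trunk. Renders equirectangular panoramas (360 x 117 pixels at one pixel
    per degree) from configurable synthetic woodland scenes, computes
    rotational image difference functions (rotIDF) between reference and
    test views with sum-of-absolute-difference or root-mean-square metrics,
    provides circular statistics for angular position data (mean vector,
    Rayleigh test, V-test toward a predicted direction, dispersion-based
    confidence intervals), and simulates view-matching foragers descending a
    cylindrical trunk under displacement and landmark-blocking conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
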