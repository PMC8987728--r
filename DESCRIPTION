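Package: corridr
Title: Characteristic Averages and Statistical Response Corridors for
    Two-Dimensional Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a characteristic average curve and statistically
    defined response corridors for collections of two-dimensional
    experimental signals such as force-displacement curves,
    acceleration-time traces, and hysteretic load-unload loops. Signals
    are re-parameterized by normalized arc length so that non-monotonic
    and hysteretic data can be averaged without segmentation, optionally
    registered with monotone cubic Hermite warping functions that align
    shared features (peaks, valleys) across signals by maximizing a
    penalized cross-correlation score, and summarized point-wise with an
    uncorrelated bivariate normal model whose elliptical confidence
    regions are merged into a corridor envelope by iso-contour
    extraction. Includes generators for reproducible synthetic signal
    families with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    mgcv,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
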