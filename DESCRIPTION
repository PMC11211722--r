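Package: erpwarp
Title: Dynamic Time Warping Latency Analysis for Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures latency differences between event-related potential
    (ERP) waveforms with dynamic time warping (DTW) and places the resulting
    area statistic into resampling-based inference. Provides a paired
    sign-flip permutation test for condition latency differences, a
    shared-sample participant bootstrap for testing temporal coupling
    between two ERP components, Fisher-Z comparison of correlations, a
    noise-robustness simulation driven by EEG-spectrum noise, a synthetic
    ERP generator with controllable latencies and cross-component coupling,
    and plain-text I/O for participant-by-time matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
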