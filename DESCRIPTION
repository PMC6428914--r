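Package: isfcs
Title: Intensity-Sorted Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of slow-scanning fluorescence correlation spectroscopy
    (FCS) measurements in heterogeneous specimens such as cell nuclei. A
    recorded two-channel photon-count trace is divided into short segments;
    each segment yields a short-sequence autocorrelation function (ACF) and a
    mean intensity, segments are sorted into region populations by reference
    intensity thresholds, and population-averaged ACFs are fitted with
    diffusion, scanned-diffusion, two-component, and reaction-diffusion
    (binding) models. Includes a Brownian-dynamics simulator of molecules
    diffusing through a 3D-Gaussian observation volume scanned on a slow
    circular orbit across regions of differing diffusion coefficient and
    reference brightness, an acquisition-design calculator for segment
    duration and scan-speed bounds, and file I/O for traces, correlation
    curves, and fit reports.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
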