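Package: spectracal
Title: Multivariate Spectral Calibration Workbench for Overlapping UV Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and stress-testing multivariate calibration models
    for two-component mixtures with strongly overlapping UV absorption spectra.
    Provides multilevel multifactorial calibration designs and Latin hypercube or
    Monte Carlo validation sampling with space-coverage diagnostics; spectral
    preprocessing (Savitzky-Golay smoothing and derivatives, standard normal
    variate, mean centering) and PCA diagnostics; NIPALS partial least squares
    with leave-one-out cross-validation; genetic-algorithm wavelength selection
    with either a penalized cross-validation fitness or an information-complexity
    (ICOMP) fitness; a small Levenberg-Marquardt-trained feed-forward network;
    multivariate curve resolution by alternating least squares under
    non-negativity; a complete evaluation suite (RMSEC/RMSECV/RMSEP, recovery
    statistics, method-comparison t and F tests); and a synthetic Beer-Lambert
    mixture generator so the whole workflow can be exercised end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
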