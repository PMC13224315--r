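Package: fractalEI
Title: Fractal BOLD Dynamics and Excitation-Inhibition Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates voxelwise Hurst exponents from BOLD-like 4D time
    series via Welch power spectra and log-log spectral-index regression,
    aggregates them within a grey-matter/MRS-voxel region of interest, and
    relates them to magnetic-resonance-spectroscopy-derived
    excitation-inhibition (Glx/GABA+) ratios with a random-intercept linear
    mixed-effects model and simulate-refit power analysis. Includes exact
    circulant-embedding simulation of fractional Gaussian noise and
    fractional Brownian motion for estimator validation, multi-echo T2*
    fitting with optimal echo combination, quality-control computations
    (framewise displacement, Dice consensus masks, exclusion rules), and a
    synthetic cohort and phantom generator so the full pipeline can be
    exercised end to end without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
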