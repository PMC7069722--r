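Package: photosync
Title: Dual-Region Spectrometer Fiber-Photometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of dual-region, spectrometer-based fiber
    photometry recordings of calcium dynamics. Per-frame emission spectra are
    linearly unmixed against fluorophore reference curves (GCaMP6f and
    tdTomato), motion-corrected by the activity-independent red channel,
    bleach-corrected with a zero-phase high-pass filter, and converted to
    dF/F. Inter-regional coupling is quantified band-wise (Morlet continuous
    wavelet decomposition over 0.05-2 Hz, Pearson correlation per band,
    Fisher-z group comparison), behavioral bouts are aligned to dF/F for
    peri-event cumulative-activity statistics, and novel-place-recognition
    discrimination ratios are scored with exclusion rules. A seeded synthetic
    session generator (spectral forward model with photobleaching, motion
    artifacts, band-limited correlated latents and exploration-locked
    transients) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
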