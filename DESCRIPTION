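Package: vrgaze
Title: Gaze and Saccade Classification for Mobile Virtual-Reality Eye
    Tracking with EEG Co-Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies continuous 3D eye-tracking streams recorded in
    virtual reality into gazes and saccades using a velocity-based
    algorithm with an adaptive median-absolute-deviation threshold and an
    explicit correction for the observer's translational movement. Gaze
    angular velocity is computed from the shift of gaze-ray hit points
    projected onto the plane orthogonal to the viewing direction, so that
    walking while looking at a fixed object yields zero eye velocity.
    Includes validity handling and interpolation of the raw stream,
    data-driven and fixed-interval segmentation for per-segment adaptive
    thresholds, event repair and outlier rejection, a two-clock drift
    alignment between eye tracker and EEG, fixation-onset event-related
    potentials (fERPs) and Morlet-wavelet spectral perturbations (fERSPs)
    with dB baselining, a trial-versus-average shift-correlation analysis
    of temporal sensitivity, and a ground-truth simulator of VR scanpaths
    and gaze-locked EEG on a drifting clock.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
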