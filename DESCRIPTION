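Package: microstatr
Title: Resting-State EEG Microstate Segmentation, Back-Fitting and Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into microstates:
    global field power (GFP) peak detection, polarity-invariant modified k-means
    clustering of peak topographies, a meta-criterion over seven cluster-validity
    indices for choosing the number of maps, and two-level (individual to group to
    population) clustering. Back-fits templates onto continuous EEG to derive the
    temporal parameters of each microstate class (global explained variance, mean
    duration, time coverage, occurrence per minute), and compares groups with a
    topographic permutation test (TANOVA), mixed-design repeated-measures ANOVA
    with Bonferroni post hoc contrasts, Pearson correlations and stepwise multiple
    linear regression with variance-inflation diagnostics. Includes a preprocessing
    chain (band-pass filter, resampling, spherical-spline channel interpolation,
    common average reference), readers and writers for EDF and plain delimited
    recordings, and a synthetic semi-Markov cohort generator with known ground
    truth for validating every stage.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
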