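Package: autotap
Title: Kinematic Analysis of Automatic Finger-Tapping Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for video-derived keypoint trajectories of
    repetitive sequential finger tapping under different attentional-focus
    conditions. Provides a synthetic trajectory generator with known ground
    truth, preprocessing (segmentation, Fourier duration normalization,
    smoothing, outlier interpolation, range-of-interest selection), a Morlet
    continuous-wavelet-transform and wavelet-transform-coherence engine with
    cone-of-influence masking, tapping-rate and FWHM-band estimation,
    inter-finger and inter-trial coherence summaries, Hilbert-envelope tapping
    amplitude and the attentional modulation index, sliding-window SVM pattern
    decoding of attentional condition, and the repeated-measures statistics
    used to evaluate them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    kernlab,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
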