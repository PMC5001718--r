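Package: natview
Title: Reliability Analysis of fMRI Responses to Naturalistic Movie Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the reliability of BOLD responses to repeated
    naturalistic movie stimulation. Provides Fourier phase scrambling of
    grayscale video for control stimuli, scene-transition (shot boundary)
    detection with block-matching motion weighting, conversion of eye-tracking
    traces into saccade-amplitude signals, construction of hemodynamic
    regressors (canonical double-gamma HRF, anti-alias filtering, resampling
    to the scanner acquisition grid), voxelwise intra- and inter-subject
    correlation mapping with Fisher z transformation, parametric group tests
    with Benjamini-Hochberg false discovery rate control, a circular-shift
    permutation null for inter-subject correlation, nuisance variable
    regression for confound removal, and a synthetic-data generator with
    known ground truth for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
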