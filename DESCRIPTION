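Package: ovpipe
Title: Optical Vulnerability Analysis of Leaf Xylem Embolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the smartphone-based optical vulnerability (OV) method:
    converts time-lapse image stacks of a dehydrating leaf into embolism event
    maps by sequential image subtraction, quantifies cumulative embolized vein
    length per unit leaf area (VLA) by calibrated skeletonization, measures
    major and minor vein density on cleared-leaf images, and fits sigmoidal
    vulnerability curves (logistic or Weibull) to estimate the water potential
    at 50% embolism with bootstrap confidence intervals. Includes a fully
    ground-truthed synthetic leaf simulator (hierarchical vein networks,
    per-segment embolism schedules, rendered noisy image stacks) so that every
    stage of the pipeline can be validated end to end, plus a command-line
    interface for the simulate/detect/curve workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    optparse,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
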