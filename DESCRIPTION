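Package: npairsopt
Title: Adaptive Optimization of Task fMRI Preprocessing Pipelines with
    NPAIRS Split-Half Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exhaustive evaluation of task-fMRI preprocessing pipelines on
    single runs using split-half NPAIRS prediction (P) and spatial
    reproducibility (R) metrics. Implements a 13-step ordered preprocessing
    pipeline (motion correction, volume censoring, RETROICOR, slice-timing
    correction, spatial smoothing, non-neuronal tissue masking, Legendre
    detrending, motion-parameter regression, global-signal PC regression,
    task-design regression, and data-driven physiological denoising) as
    composable operators, Gaussian naive Bayes and canonical variates
    decoders, reproducible Z-scored statistical parametric maps, CONS/FIX/IND
    pipeline selection rules with motion-artifact rejection, FDR-thresholded
    activation-overlap validation, and split-half behavioural partial least
    squares with bootstrap pipeline comparison. A synthetic 4D BOLD cohort
    generator with known signal and noise composition makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
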