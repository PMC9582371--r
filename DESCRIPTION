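Package: scfmri
Title: Simulation and Analysis of Value-Based Self-Control fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing task fMRI experiments on
    value-based dietary self-control. Generates BIDS-like synthetic datasets
    (food-rating behaviour, BOLD volumes with AR(1) noise and low-frequency
    drift, motion traces, region masks) with known ground truth; classifies
    participants into self-controllers and non-self-controllers from their
    choices; builds first-level general linear models with reaction-time
    boxcars and sequentially orthogonalized parametric modulators of goal
    value, health and taste; fits them with AR(1) prewhitening and runs
    one- and two-sample group tests with uncorrected and false-discovery-rate
    thresholds; extracts region-of-interest signal by per-subject peak voxel
    or mask average, including a white-matter control quantifying the
    circularity bias of non-independent peak selection; and performs
    two-stage psychophysiological-interaction connectivity analysis with
    ridge-regularized hemodynamic deconvolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
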