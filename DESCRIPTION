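Package: ocufit
Title: Fluorescence Lifetime Imaging Ophthalmoscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of time-correlated single photon counting (TCSPC)
    data from fluorescence lifetime imaging ophthalmoscopy (FLIO).
    Provides static and adaptive photon binning, forward evaluation of
    multi-exponential, stretched-exponential, spectrally global, layered
    and crystalline-lens-corrected decay models with instrument response
    function convolution and incomplete-decay correction, reduced
    chi-square fitting with a two-stage optimisation (differential
    evolution for a global initial solution, bound-constrained
    Nelder-Mead per pixel) and variable projection of the linear
    parameters, reflection-artifact detection and iterative outlier
    treatment, amplitude-weighted mean lifetimes, spatial filtering,
    ETDRS-grid region-of-interest statistics, and histogram-class group
    comparison with Wilcoxon rank-sum tests and ROC analysis. A
    synthetic TCSPC data simulator with known ground truth is included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'binning.R'
    'core_io.R'
    'decay_models.R'
    'fitting.R'
    'postprocess.R'
    'group_stats.R'
    'ocufit-package.R'
    'simulator.R'
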