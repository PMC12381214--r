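Package: catchbond
Title: Single-Molecule Force Spectroscopy Analysis and Multi-State
    Catch-Bond Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy based
    single-molecule force spectroscopy (AFM-SMFS) of receptor:ligand
    complexes that unbind through multiple pathways. Provides freely
    rotating chain and worm-like chain polymer elasticity models,
    transformation of force-extension curves into contour-length space,
    automated curve filtering and unfolding-fingerprint identification,
    Gaussian-mixture classification of rupture forces into unbinding
    pathways, force-dependent off-rate estimation by the histogram
    transformation method with Dudko-Hummer-Szabo and Bell-Evans energy
    landscape fitting, a reversible three-state kinetic Monte Carlo
    simulator of bond rupture under constant-speed and force-clamp
    protocols with random-search fitting of hidden inter-state
    transition barriers, nonparametric statistical protocols for binned
    bond lifetimes, and Hill-equation equilibrium titration fitting.
    Synthetic data generators with known ground truth make every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
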