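Package: grouppca
Title: Memory-Efficient Group-Level PCA for Temporally Concatenated Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Solvers for group-level principal component analysis of very large
    temporally concatenated multi-subject datasets, as used to reduce fMRI data
    before group independent component analysis. Provides exact eigenvalue
    decomposition paths in either data dimension, subsampled voxel and
    subsampled time approximations (SVP, STP) for fast initialization, a
    convergence-checked randomized block Lanczos solver, multi power iteration
    (MPOWIT) with an enlarged projecting subspace, and expectation-maximization
    PCA, each runnable in stacked (in-memory) or un-stacked (one subject at a
    time) mode with explicit dataload accounting. Includes a synthetic
    multi-subject generator with a planted basis and spectrum for validation,
    brain-mask utilities for 4D volumes, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
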