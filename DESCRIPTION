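Package: swiqsm
Title: Apparent Susceptibility Mapping from Clinical SWI Phase and Diagnostic
    Statistics for Parkinsonism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing maps of apparent magnetic susceptibility
    from clinical susceptibility-weighted imaging (SWI) magnitude and
    high-pass-filtered phase volumes, and for the downstream group statistics
    used to separate progressive supranuclear palsy, multiple system atrophy,
    Parkinson's disease and controls from deep gray nuclei susceptibility.
    Includes a forward-physics digital phantom simulator (dipole field,
    scanner-style homodyne high-pass filter, complex noise), the
    reconstruction chain (mask erosion, Laplacian phase unwrapping, V-SHARP
    background field removal, iLSQR dipole inversion), ROI extraction with
    CSF referencing, a structured cohort simulator, and the statistical layer
    (ANCOVA with LSD pairwise comparisons, Mann-Whitney U, ROC with DeLong
    confidence intervals, equal-prior linear discriminant analysis with
    leave-one-out cross-validation, partial correlations and Bonferroni
    correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    nortest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    emmeans,
    optparse
Config/testthat/edition: 3
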