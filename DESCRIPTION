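Package: conngrad
Title: Connectopic Mapping of Functional Connectivity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise connectopic mapping of a region of interest from
    resting-state fMRI: connectivity fingerprints against an SVD-reduced
    whole-brain reference, eta-squared similarity between fingerprints,
    Laplacian-eigenmap decomposition into ordered spatial connectivity
    modes, and trend surface models (polynomial spatial basis fitted by
    empirical-Bayes linear regression) summarising each mode with a small
    coefficient vector. Includes a synthetic-phantom generator with
    planted spatial gradients for validation, and the group-level
    statistical toolkit used with such modes: spatial and
    coefficient-space correlations against reference density maps,
    ICC(2,k) test-retest reliability with bootstrap confidence intervals,
    within- versus between-subject permutation tests, and omnibus
    likelihood-ratio tests of coefficient vectors against categorical and
    continuous outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
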