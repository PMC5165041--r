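Package: t1qc
Title: Automated Quality Assessment of T1-Weighted Structural Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated quality control for high-resolution T1-weighted
    structural brain MRI volumes. Builds background, eye and ring masks
    from tissue probability maps, extracts volumetric features (intensity
    and tissue-probability histograms, a gray/white-matter contrast
    t-score) and artifact-specific features targeting eye-movement
    ghosting, motion ringing and wrap-around aliasing, and classifies
    volumes as usable or not-usable with a balanced, repeated,
    cross-validated support vector machine protocol including a
    permutation null. A parametric head-phantom generator with controlled
    artifact injection makes the full pipeline testable without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    EBImage,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
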