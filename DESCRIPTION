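Package: mwfr
Title: Myelin Water Fraction Mapping by Multi-Echo T2 Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise myelin water fraction (MWF) estimation from multi-echo
    T2 decay data by non-negative least squares (NNLS) spectrum inversion,
    with multi-compartment phantom simulation, lesion and normal-appearing
    white matter region-of-interest statistics (including two-way random
    intraclass correlation for rater reliability), and the cohort-level
    statistics that relate lesion/NAWM MWF ratio to change in Timed Up and
    Go mobility scores after a walking intervention in multiple sclerosis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
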