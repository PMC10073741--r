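Package: aortaflow
Title: Whole-Aorta 4D Flow MRI Analysis of Tortuosity, Helicity and
    Turbulent Kinetic Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for regional hemodynamic analysis of whole-aorta 4D flow
    MRI. Builds phase-contrast MR angiograms from magnitude and velocity
    data, segments the aortic lumen, extracts an ordered centerline,
    partitions the aorta into ascending, descending, suprarenal and
    infrarenal abdominal regions, and computes per-region tortuosity,
    diameter, absolute local normalized helicity, turbulent kinetic energy
    from the motion-encoded magnitude signal model, spatial-mean velocity
    and Reynolds number. Includes offline phase-wrap and background
    phase-offset corrections, cohort-level statistics (normality-gated
    group comparisons, Spearman correlations, linear regression), and a
    synthetic 4D flow phantom generator with analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
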