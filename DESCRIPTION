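Package: ssnPoro
Title: Normalized Solid Stress Imaging in Tumors from Ultrasound
    Poroelastography
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical model of growth-induced solid stress in spherical
    tumors and the associated ultrasound-poroelastography imaging method
    for the normalized solid stress (SSn). Provides the closed-form
    fluid-pressure and solid-stress radial profiles of a poroelastic
    spherical inclusion under creep compression, Eshelby
    equivalent-inclusion boundary stresses, a seeded synthetic phantom
    generator (2-D stress maps and longitudinal treated/untreated
    cohorts), a reconstruction pipeline that fits the spatial-distribution
    parameter alpha and produces SSn maps and peak-SSn estimates, and
    nonparametric (Kruskal-Wallis) cohort statistics, together with a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
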