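Package: pfasval
Title: Quantitative Method Validation for PFAS in Dried Blood Spots
Version: 0.1.0
Authors@R:
    person("Analytical", "Methods Lab", email = "methods@example.org",
           role = c("aut", "cre"))
Description: A validation toolkit for targeted LC-MS/MS quantification of
    per- and polyfluoroalkyl substances (PFAS) in dried blood spot (DBS)
    microsamples. Implements data-driven weighted calibration with Mandel
    and lack-of-fit model-order selection, Hubaux-Vos detection limits with
    Currie weighting for heteroscedastic data, signal-to-noise based LOD
    extrapolation, cyclic intra- and inter-day accuracy and precision by
    back-calculation, matrix effect / extraction recovery / process
    efficiency decomposition, stability ANOVA over storage time and
    temperature, full-factorial extraction optimization analysed by PCA and
    multiple linear regression, standard-addition quantification, and Blue
    Applicability Grade Index (BAGI) practicability scoring. A synthetic
    data generator reproduces the statistical structure of a 25-analyte
    DBS validation study so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
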