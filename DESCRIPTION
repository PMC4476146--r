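Package: metaburden
Title: Quantitative Modeling of Liver-Metastasis Burden from Optical Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify experimental liver-metastasis burden from
    bioluminescent and fluorescent imaging of intrasplenic-injection mouse
    models. Provides linear calibration of optical signal to cell number,
    estimation of the colonizing fraction (Fc) and colony doubling time (Td)
    under single-founder exponential growth, sphere-model tumor volumes and
    clone-level phenotype summaries, a stochastic (Fc, Td)-parameterized
    colonization simulator with reproducible seeding, inverse estimators with
    simulation-based parameter-recovery reports, and a synthetic ex vivo
    fluorescence image renderer with robust colony detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
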