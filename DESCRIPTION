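Package: ichneutro
Title: Neutrophil-Subset Severity Analysis for Spontaneous Intracerebral Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of the computational pipeline of a
    pilot spontaneous intracerebral hemorrhage (sICH) study: CT-based
    hematoma and perihematomal edema volumetry (bedside ABC/2 estimation and
    semiautomated dual-clustering segmentation), circularity-index scoring of
    NET-forming neutrophils on fluorescence blood smears, flow-cytometry
    quadrant counting of DEspR+CD11b+ neutrophils, and the Spearman /
    Bonferroni / power severity analysis over the packaged 13-patient
    cohort. Seeded synthetic-data generators provide CT phantoms, smear
    images, flow event mixtures and copula cohorts with known ground truth,
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    tiff,
    pracma,
    igraph,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
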