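Package: immunoflux
Title: Multi-Assay Analysis of Mitochondrial Function and Autophagy in Aging CD4+ T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing CD4+ T cells from young and old donors
    across five assay modalities: reference-channel normalization and evidence-filtered
    ratio statistics for multi-plex isobaric-tag (iTRAQ) protein quantification;
    Z-transformation, Z-ratio differential statistics and parametric gene-set
    enrichment (PAGE) for expression microarrays; coupling-control analysis of
    high-resolution respirometry traces with derivation of the Bioenergetic Health
    Index and covariate-adjusted group comparison; rule-based morphometric
    classification of autophagosomes and autolysosomes from electron-microscopy
    annotations; and intensity gating of mitophagy-dye flow cytometry. Seeded
    synthetic-data generators emulate the statistical structure of each modality with
    recorded ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
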