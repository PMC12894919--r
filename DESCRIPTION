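Package: co2fix
Title: Rule-Based Prediction of Microbial CO2 Fixation Pathways from KEGG
    Orthology Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the presence or absence of the seven known natural CO2
    fixation pathways (CBB, rTCA, WL, 3HP, 3HP/4HB, DC/4HB, rGly) in microbial
    genomes from their KEGG Orthology (KO) annotation, using a curated,
    machine-readable set of marker-KO rules built from three logical
    quantifiers (one_of, all_of, at_least). Includes a parser for KofamScan
    detail-TSV output implementing the adaptive-threshold / top-hit-fallback
    KO assignment rule, per-pathway precision/recall/F1 benchmarking against
    curated label matrices, a seeded synthetic-corpus generator with known
    ground truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
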