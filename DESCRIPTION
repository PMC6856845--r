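Package: hitsieve
Title: Triage of Assay-Technology Interference Compounds in High-Throughput Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates primary and counter-screen (artefact) high-throughput
    screening results into technology-interference labels (CIAT/NCIAT),
    predicts interference from 1024-bit ECFP4 fingerprints with a random
    forest classifier, scores promiscuity with the Binomial Survivor
    Function, and flags PAINS substructures. Includes a seeded synthetic
    campaign generator with planted interference chemotypes and the full
    comparison protocol: leave-one-assay-out evaluation, Set A/Set B splits,
    label-randomization controls, assay-subsampling curves for the BSF, and
    nearest-neighbor similarity error analysis. Chemistry primitives
    (SMILES parsing, Morgan fingerprints, PAINS matching) are delegated to
    RDKit through a bundled Python helper.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC
SystemRequirements: Python (>= 3.8) with RDKit on PATH as 'python'
Config/testthat/edition: 3
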