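Package: TDCscreen
Title: Post-Metabolic Screening of Thyroid-Disrupting Chemical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated workflow for evaluating the endocrine-disrupting
    activity of hepatic biotransformation products. Combines combinatorial
    phase I/II biotransformant prediction from elemental-composition reaction
    deltas, LC-MS/MS feature annotation with fragment-coverage scoring,
    modified-cosine molecular networking with parent-subnetwork annotation,
    reporter-gene assay normalization with an agonist decision rule, and the
    supporting univariate statistics. Ships a synthetic-experiment generator
    with known ground truth so every stage is testable without raw
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'isotopes.R'
    'chemcore.R'
    'transformations.R'
    'AllClasses.R'
    'msio.R'
    'annotate.R'
    'network.R'
    'assay.R'
    'stats.R'
    'synth.R'
    'pipeline.R'
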