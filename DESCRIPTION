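Package: tmtRuler
Title: Per-Cell Protein Copy Numbers from TMT SPS-MS3 Proteomics via the
    Histone Proteomic Ruler
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns MaxQuant-style protein-group tables from isobaric-label
    (TMT) SPS-MS3 experiments into absolute per-cell protein copy numbers by
    allocating summed MS1 intensities across reporter channels and anchoring
    total histone signal to the cell's DNA mass (the proteomic ruler).
    Provides the downstream analysis stages: per-cell protein content,
    replicate quality control, empirical-Bayes moderated t-statistics with
    Storey q-values, fold-change-distribution significance classes,
    hypergeometric gene-set overrepresentation with a two-population
    background, and global summaries (PCA, population correlations,
    proteome mass fractions, gene-set copy sums). A synthetic-data generator
    emulating a multi-population T-cell TMT design makes the entire pipeline
    testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
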