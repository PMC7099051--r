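Package: hybQC
Title: Quality Control and Locus Filtering for Target-Capture Phylogenomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locus- and sample-level quality control for Hyb-Seq (target
    capture plus genome skimming) phylogenomic datasets, with an emphasis on
    degraded herbarium material. Provides capture-success and recovery
    statistics, a composite coverage score (representativeness x completeness
    x evenness), gap-threshold trimming optimized for the proportion of
    parsimony-informative characters, tree-based locus filters (outlier-leaf
    removal, low-support branch contraction, root-to-tip clock statistics,
    gene-tree/species-tree concordance), a deterministic synthetic-data
    generator with planted ground truth, and a pipeline that chains the
    stages in the order used in practice.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Phylogenetics, QualityControl, Alignment, Software
RoxygenNote: 7.3.3
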