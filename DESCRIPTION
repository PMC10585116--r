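Package: cladetax
Title: Cladal Taxonomic Annotation of Amplicon Sequence Variants on
    Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rescues taxonomic classifications for 16S rRNA amplicon
    sequence variants (ASVs) that a naive Bayesian classifier (NBC) left
    unassigned.  Reference tips of a phylogenetic tree carrying curated
    ranked lineages (e.g. Living Tree Project type strains) propagate
    their labels rootward: every internal node receives the most specific
    lineage congruent across its reference descendants under a
    configurable majority-rule threshold, and each unknown ASV tip is
    annotated from its nearest labeled ancestor.  The cladal annotation
    is then merged with the NBC table, filling only ranks the classifier
    failed to assign.  Includes midpoint rooting, reference-tip pruning,
    nested-label collapsing, a planted-clade simulator providing ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    phytools,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
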