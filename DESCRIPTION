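Package: myxotax
Title: Nested Taxonomic Delineation and Biogeography of 16S rRNA Gene
    Sequence Collections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Meta-analysis toolkit for large 16S rRNA gene sequence
    collections of myxobacteria (order Myxococcales): sequence quality
    control and strain-level deduplication, pairwise identity and Kimura
    two-parameter distances under pairwise deletion, nested four-rank
    taxonomic delineation (species/genus/family/suborder) by fixed
    identity thresholds with complete-linkage clustering and optional
    tree-guided monophyly refinement, abundance and habitat-specificity
    classification across ten environmental categories, analytic
    rarefaction with Good's coverage, and a synthetic sequence-community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
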