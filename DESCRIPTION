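Package: funcdiv
Title: Functional Bias in Molecular Evolution Rates of Duplicated Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing whether the molecular evolution
    rate (dN/dS) of gene pairs retained after a whole-genome duplication
    depends on their biological function. Parses Gene Ontology (OBO) and
    annotation (GAF) files, derives each duplicate pair's most specific
    shared functions, computes Resnik/optimal-assignment functional
    similarity between pairs, clusters pairs into functional groups with
    Ward's method and a minimum-size tree cut, estimates per-pair dN and dS
    with a Nei-Gojobori style counting method from codon alignments, and
    compares groups with ANOVA, Tukey HSD and parent-child GO term
    enrichment. Includes a synthetic-study generator with planted functional
    families and known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
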