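Package: phenoassert
Title: Annotation Consistency and Rule-Based Phenotype Inference for
    Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A workbench for auditing and completing microbial genome
    functional annotations. Propagates functional terms between genomes by
    strict sequence-similarity thresholds, detects candidate genes through
    bidirectional best hits (BBH), asserts metabolic pathway presence with a
    three-valued (Kleene) status of asserted / unknown / not asserted,
    predicts organism phenotypes (e.g. amino-acid prototrophy, aerobiosis,
    carbon-source utilisation) from boolean rules over pathway statuses, and
    compares predictions against organism metadata. Cross-classification
    consistency reports relate KO terms to COG/Pfam/TIGRfam family
    combinations and to within-genome paralog clusters computed with the
    Markov Cluster Algorithm. A deterministic synthetic-fixture generator
    produces complete miniature annotation sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
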