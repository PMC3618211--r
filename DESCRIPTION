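Package: ppirules
Title: High-Precision Rule-Based Protein-Protein Interaction Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts protein-protein interactions (PPIs) from annotated
    biomedical sentences with eight high-precision dependency and lexical
    rules over collapsed-Stanford dependency parses, including negation
    handling. Provides corpus preprocessing (protein masking, parenthetical
    stripping, clause splitting, candidate-pair enumeration), a CoNLL-U
    reader with Universal Dependencies collapsing, a 67-keyword interaction
    lexicon with morphological matching, per-instance and per-relation
    precision/recall/F evaluation with minimum-instances-per-relation
    (MIpR) stratification, a generic two-tier classifier pipeline with
    dependency-chain bigram features, worked-example fixtures, and a
    synthetic annotated-corpus generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
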