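Package: domainforest
Title: Domain-Centric Feature Tables and Random-Forest Prediction for
    Protein Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms protein-domain annotations -- assembly
    stoichiometry and symmetry, domain-domain interaction interfaces,
    liquid-liquid phase separation (condensate) annotations, GO/PO
    annotation records, and transcription-factor binding data -- into
    mixed categorical feature tables keyed by Pfam domains.  Encodes
    protein and DNA sequences in reduced group alphabets with trimer
    frequency profiles, maps binding sites onto gene features with
    half-open interval semantics, and runs a bagged random-forest
    classification protocol over stratified evaluation schemes.
    Post-hoc structure analysis includes factor analysis of mixed data,
    a mixed-type association matrix (Pearson, correlation ratio,
    Cramer's V), and greedy hotspot-style association rules.  A
    deterministic synthetic fixture generator produces miniature
    schema-conformant snapshots of every input table so the complete
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    mclust,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
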