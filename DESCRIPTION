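Package: eventpairs
Title: Recursive Pairwise Extraction of Biomedical Events from Annotated Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts typed biomedical events (gene expression, binding,
    regulation and related types) from dependency-parsed text annotated in
    the BioNLP Genia standoff format. Events are recovered as (trigger,
    argument) pairs by a single multi-class classifier built from
    cost-asymmetric one-vs-rest linear support vector machines over sparse
    lexical, window and dependency-path (E-walk/V-walk) features; nested
    regulation events are extracted recursively by a score-ordered agenda
    with cycle censoring, and secondary arguments are added by binary
    post-classifiers (Binding theme fusion, Regulation cause assignment).
    Includes standoff (.txt/.a1/.a2) readers and writers, an
    approximate-span recursive-match evaluator, a deterministic synthetic
    corpus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
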