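Package: pheno2go
Title: Cross-Ontology Phenotype-to-Function Term Mapping and Phenotype
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps Human Phenotype Ontology (HPO) terms to Gene Ontology
    (GO) terms from the frequency with which the two vocabularies are
    co-annotated to the same genes, using a Dice-style co-occurrence
    similarity. Unreliable mappings are removed with a permutation-null
    procedure: annotation tables are randomized by relabeling gene
    identities, co-occurrence similarity distributions are compared with
    two-sample Kolmogorov-Smirnov tests over a grid of similarity and
    co-annotation-count thresholds, and the lowest significant threshold
    pair is selected. Surviving mappings transfer HPO terms to proteins
    from their existing GO annotations, and predictions are scored with
    CAFA-style protein-centric (Fmax, weighted Fmax, Smin) and
    term-centric (AUROC) metrics under true-path-rule propagation.
    Includes OBO 1.2 parsing, information-accretion estimation, synthetic
    data generators with planted co-annotation signal, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
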