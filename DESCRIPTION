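Package: funkfams
Title: Discovery and Metagenomic Profiling of Function-Unknown Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens a protein-family catalog for robustly defined, full-length
    families that carry no domain annotation in curated databases
    (function-unknown families, "FUnkFams"), ranks them by phylogenetic
    breadth across named taxonomic ranks, quantifies their presence and RPKG
    abundance in shotgun metagenomes from tabular read alignments, and tests
    family presence for association with sample covariates using stratified
    logistic regression with Benjamini-Hochberg FDR control. Includes a seeded
    synthetic-data generator that emits complete, internally consistent
    fixtures with a ground-truth manifest, and an end-to-end pipeline driver
    with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
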