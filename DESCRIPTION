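Package: epivote
Title: Linear Epitope Mapping by Propensity Profiles and Multi-Predictor
    Consensus Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An immunoinformatics toolkit for characterizing allergen
    protein sequences and mapping candidate linear B-cell and MHC class II
    T-cell epitopes. Provides FASTA ingestion and CDS translation,
    ProtParam-style physicochemical profiling (molecular weight,
    theoretical pI, GRAVY, aliphatic and instability indices), a
    PROSITE-syntax motif scanner, classical sliding-window propensity
    predictors (Kolaskar-Tongaonkar antigenicity, Parker and Hopp-Woods
    hydrophilicity, Emini surface probability, Karplus-Schulz
    flexibility), and residue-level k-of-n consensus voting that combines
    epitope interval tracks from multiple predictors or HLA alleles into
    consensus epitopes. Includes seeded generators for synthetic
    sequences, predictor tracks and per-allele binder lists, plus an
    end-to-end reporting pipeline with TSV, BED, GFF3 and JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
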