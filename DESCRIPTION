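Package: crisprCrossTalk
Title: Cross-System CRISPR Guide Sharing Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hosts carrying co-occurring type I-F and
    type III-B CRISPR-Cas systems, where type III-B effector complexes can
    load type I-F crRNAs and thereby counter phage mutants that escape type
    I-F interference through PAM mutations. Provides spacer orientation and
    strand-bias statistics with an annotation-derived null, a stochastic
    universal sampling Monte Carlo envelope for acquisition versus gene
    expression, small-RNA read classification for pre-crRNA processing
    detection, protospacer/PAM/seed scanning with per-system interference
    competence prediction, pairwise phage genome comparison with escape
    mutation classification, in-silico PCR, and assay quantification (log
    cfu with censoring, efficiency of plaquing, Most Probable Number
    titers, relative transcript levels). A synthetic-data generator with
    complete truth tables supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
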