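Package: loopmotifs
Title: Discovery of Over-Represented Structural Motifs in Protein Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simplifies protein backbones into structural-letter sequences
    with a structural-alphabet hidden Markov model, extracts overlapping
    four-letter words from loop regions, computes exact over-representation
    statistics of words within protein groups through a deterministic
    finite automaton embedded in a Markov chain, classifies words as
    ubiquitous or group-specific, and scores their correspondence with
    interval functional annotations. Includes rigid-body fragment
    superposition and a synthetic-data generator so every stage of the
    pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
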