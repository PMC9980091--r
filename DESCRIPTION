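Package: riboshift
Title: Modeling and Correction of Ligation Biases in Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ribosome profiling libraries carry sequence-dependent artifacts
    introduced by nuclease digestion and adapter ligation that distort
    codon-level footprint counts. riboshift models per-codon footprint counts
    with a negative binomial regression that separates biological effects
    (A/P/E-site codon identity) from technical effects (digestion lengths,
    footprint end sequences and their interactions, GC content), and inverts
    the fitted technical terms into per-footprint correction factors that
    preserve total library size. The package also ships a footprint simulator
    with known codon dwell weights and end-sequence recovery probabilities,
    A-site offset inference from start/stop-codon metagene profiles (including
    disome footprints protected by collided ribosomes), differential A-site
    occupancy testing between conditions, and bias diagnostics
    (position-importance profiles, metagene plots, pause scores, and a
    mean-variance check of the count distribution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
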