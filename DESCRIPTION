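Package: mockbench
Title: Benchmarking DNA Extraction Methods with Mock Microbial Communities
Version: 0.1.0
Authors@R: person("Dana", "Whitfield", email = "dwhitfield@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how faithfully a DNA extraction and 16S rRNA
    amplicon sequencing protocol represents a mock microbial community of
    known composition. Computes expected read proportions from cell
    fractions and 16S rRNA gene copy numbers, tests observed counts
    against expectation with a Dirichlet-multinomial likelihood-ratio test
    calibrated by parametric bootstrap, scores representation and
    reproducibility by Euclidean distances with rank-based pairwise
    comparisons, analyses DNA yields with a balanced split-plot ANOVA and
    Tukey HSD compact letter displays, and filters barcoded amplicon reads
    (Hamming-distance demultiplexing, IUPAC-aware primer matching,
    length/ambiguity/homopolymer rules). A synthetic-data generator
    produces count tables, yield tables and barcoded reads with the
    statistical structure these analyses assume, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
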