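Package: chimeracas
Title: Design and Screen Quantification for Chimeric Cas12a Nuclease Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and quantifying domain-recombination
    (chimeragenesis) libraries of Cas12a-type CRISPR nucleases. Computes
    multiple-sequence-alignment conservation profiles and selects crossover
    junctions under spacing constraints, enumerates one- and two-crossover
    chimera designs and realizes them as coding sequences and Gibson-style
    assembly fragments, quantifies bacterial cutting/editing/transformation
    screens and T7E1 indel assays, scores PAM preferences from paired
    targeting/non-targeting amplicon libraries, and designs mismatch
    off-target cassette panels with read-count summaries. A seeded
    synthetic-data generator emulates the statistical structure of each
    input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
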