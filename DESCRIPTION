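Package: codonopt
Title: Codon Optimality, tRNA Adaptation and Codon-Dependent mRNA Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wobble-aware matching of codons to measured tRNA anticodon
    abundances, expression-based tRNA adaptation index (etAI) and codon
    adaptation index (CAI) scoring of coding sequences, per-transcript
    decoding rates from ribosome A-site dwell times, mRNA half-life
    estimation from expression time-courses, and codon stabilization
    coefficients (CSC) linking codon content to mRNA stability. Includes a
    deterministic synthetic-data generator so every analysis stage can be
    validated against known ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
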