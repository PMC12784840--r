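Package: mitocub
Title: Codon Usage Bias Diagnostics for Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative codon usage bias analysis for AT-rich invertebrate
    mitochondrial genomes. Parses GenBank flat files, extracts and codonizes
    protein-coding genes under the invertebrate mitochondrial genetic code
    (translation table 5, including incomplete stop codons and atypical start
    codons), and computes relative synonymous codon usage (RSCU) with
    preference classification, positional GC composition, Wright's effective
    number of codons (ENC) with the expected-ENC curve and ENC ratio,
    GC12-on-GC3 neutrality regressions with slope confidence intervals, and
    parity rule 2 (PR2) coordinates at fourfold-degenerate sites. Includes a
    seeded synthetic mitogenome generator with analytic ground truth so every
    stage of the pipeline can be validated offline, and a one-call pipeline
    that emits plot-ready tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
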