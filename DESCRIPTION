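Package: recodon
Title: Silencing-Resistant Transgene Design by Constrained Reverse
    Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing synthetic coding sequences that resist
    host transgene silencing, following the strategy used to recode the
    firefly and Renilla luciferase reporters for expression in sugarcane.
    Builds host codon-usage tables from coding-sequence sets or
    Kazusa-style frequency tables, performs threshold-filtered Monte
    Carlo reverse translation, screens candidates for excluded features
    (degenerate IUPAC motifs, A/T runs, direct and inverted repeats,
    palindromes, restriction sites, GC-content breaches) and repairs them
    iteratively while preserving the encoded protein.  Also provides the
    accompanying verification metrics (GC content, nucleotide identity,
    codon-change summaries), transgene-discriminating qPCR primer design,
    dilution-series amplification efficiency, and comparative-CT relative
    quantification, plus seeded synthetic-data generators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
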