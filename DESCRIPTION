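Package: minigenomics
Title: Comparative Genomics of Genome Miniaturization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genome size reduction across related species:
    genic/intergenic partitioning of annotated assemblies, transposable-element
    divergence landscapes with Jukes-Cantor insertion-time dating, Fisher-test
    screening of gene-family expansion and contraction from Pfam domain counts,
    a relative-gene-length statistic for calling size-reducing and
    size-increasing single-copy orthologs with hypergeometric pathway
    enrichment, and TPM-based expression summaries including a miniature
    weighted co-expression network with intramodular-connectivity hub ranking.
    A synthetic-data module generates every input format with planted ground
    truth so each stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
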