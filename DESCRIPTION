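Package: estpop
Title: Post-Assembly Analysis of Population-Level EST Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing de novo EST (expressed sequence tag)
    assemblies built from pooled population samples. Provides column-wise
    SNP calling from contig multiple alignments under loose and strict
    criteria, variant-region detection, transition/transversion and
    synonymous/non-synonymous classification via best protein hits, the
    ortholog hit ratio as a transcript-completeness metric, Watterson-style
    relative diversity statistics corrected for read depth, best-hit
    association-graph clustering of unigenes, and a synthetic EST assembly
    generator with a complete truth table for validating every stage.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
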