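Package: mitocall
Title: Mitochondrial Genome Characterization and Echolocation Call Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of small circular
    mitochondrial genomes and of frequency-modulated echolocation calls.
    Builds gene organization tables (sizes, start/stop codon classes,
    intergenic spacers and overlaps) from GenBank flat files or feature
    tables, computes nucleotide composition and AT/GC skew per gene and gene
    class, tabulates codon usage (RSCU) over concatenated protein-coding
    genes under the vertebrate mitochondrial code, assigns cloverleaf
    secondary structures to annotated tRNAs, computes pairwise p- and
    model-corrected distances with neighbor-joining trees and bootstrap
    support, and extracts per-pulse call parameters (sweep endpoints, peak
    frequency, duration, inter-pulse interval) from recordings.  Includes
    seeded generators for annotated synthetic mitogenomes and synthetic FM
    call trains with known ground truth, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    jsonlite
Config/testthat/edition: 3
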