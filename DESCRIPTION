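Package: ribothrough
Title: Detection and Quantification of Stop-Codon Readthrough from
    Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates inter-stop codon regions (ISRs) on mRNA transcripts,
    maps ribosome footprint reads by exact matching or from transcript-space
    alignments, assigns P-sites, and applies a four-criterion filter to call
    translational readthrough. Also provides 3-nucleotide periodicity and
    reading-frame analysis, construction of readthrough-variant protein
    databases with in silico tryptic digestion and extension-specific
    peptide mapping, dual-luciferase readthrough-efficiency quantification,
    and a synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
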