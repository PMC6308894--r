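Package: primercov
Title: Zoned-Mismatch Coverage Evaluation and Design of Degenerate
    Metabarcoding Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In silico evaluation of degenerate (IUPAC-coded) PCR primers
    against taxonomically annotated reference alignments of the COI
    barcoding locus. Mismatches are counted in two zones -- the four bases
    closest to the primer 3' end, where they block polymerase extension,
    and the 5' remainder -- and primer coverage is reported over a nested
    grid of mismatch-tolerance criteria, overall and per taxonomic class.
    Also provides consensus-based degenerate primer design from per-column
    base frequencies, universal-tail poor-fit checks, binding-site and
    amplicon prediction on unaligned sequences, and a mock-community
    sequencing simulator with a binomial detection-probability model
    linking relative template concentration and sequencing depth to taxon
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
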