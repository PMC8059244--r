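Package: polyvax
Title: Polyepitope Neoantigen DNA Vaccine Insert Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design of string-of-beads polyepitope DNA vaccine inserts from
    annotated somatic missense variants. Implements neoantigen prioritization
    by median predicted MHC class I binding affinity with variant-allele-
    fraction, expression and mutant/wild-type fold-change filters; long
    (20-25-mer) epitope extraction with native flanking residues; junctional
    epitope enumeration and an epitope-ordering optimizer that minimizes
    predicted junctional binders (exact search, subset dynamic programming,
    or simulated annealing depending on problem size); assembly of the final
    construct with an N-terminal uncleavable G76V ubiquitin degron and an
    optional C-terminal HA tag; and codon-usage-driven reverse translation
    with restriction-motif avoidance. Includes a seeded synthetic-scenario
    generator with planted ground truth for end-to-end validation, and small
    utilities for cytotoxicity, tumor-volume and ELISpot readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
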