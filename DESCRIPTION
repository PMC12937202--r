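Package: snapPCR
Title: Species-Specific Multiplex PCR Panel Design from Barcode Alignments
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs multiplex species-identification PCR panels from a
    species-labelled barcode-gene alignment (e.g. COI). Scans the alignment
    for fixed, species-specific single-nucleotide polymorphisms and for
    pan-species conserved windows; designs one universal forward primer and
    per-species reverse primers anchored on a diagnostic SNP at the 3'
    terminus; assembles a panel whose amplicons form a resolvable size
    ladder; validates panels by in-silico multiplex PCR with 3'-mismatch
    extension blocking and renders a virtual agarose gel. Includes a
    synthetic alignment generator with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
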