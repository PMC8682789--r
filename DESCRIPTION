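Package: attrace
Title: Detect Excisable Prophages from Overlapping Split-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes active (excisable) prophages and other site-specifically
    recombining mobile elements in prokaryotic genomes from short-read alignments.
    Split reads that span an attB (excision) or attP (circularization) junction
    align locally to two reference loci with overlapping query intervals; the
    overlap is the att core shared by attL and attR. The package extracts
    candidate split reads and discordant pairs from SAM by FLAG/CIGAR semantics,
    verifies them by seeded local re-alignment, infers attachment-site endpoints,
    clusters evidence into candidate prophages with tabular reports, supports
    fragmented (contig-level) assemblies, estimates between-condition fold-changes
    of excision activity, and ships a read-mixture simulator with truth alignments
    for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
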