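Package: mitocub
Title: Codon Usage Bias Analysis for Organelle Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens coding sequences from GenBank flat files or FASTA,
    computes codon usage statistics (codon counts, RSCU, positional GC
    content, synonymous third-position base frequencies, Wright's effective
    number of codons, CAI, CBI, Fop), runs mutation-versus-selection
    diagnostics (neutrality regression of GC12 on GC3, ENC plot against the
    composition-only expectation, PR2 parity plot, Pearson correlation
    matrices), identifies optimal codons from ENC-ranked expression pools
    via pooled RSCU differences, and clusters genomes by RSCU profiles.
    Includes a seeded synthetic CDS generator with known mutation or
    selection regimes for end-to-end validation, and an orchestrated
    pipeline that writes tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
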