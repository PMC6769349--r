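Package: grfevol
Title: Gene-Family Characterization and Molecular-Evolution Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reusable pipeline for plant gene-family studies of the
    growth-regulating factor (GRF) kind: conserved-domain family scanning
    with protein physicochemical statistics, bidirectional best-hit
    ortholog and threshold paralog calling from exact pairwise alignment,
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    sliding-window selection profiles and Ks-based divergence dating,
    neighbor-joining phylogenies with bootstrap support, promoter
    cis-element censuses from an editable IUPAC motif dictionary, and
    qRT-PCR relative-expression statistics. Ships a seeded synthetic-data
    engine (codon evolution under a target omega and Ks, duplicating
    families with known split times, planted promoter motifs, replicated
    Ct tables) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
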