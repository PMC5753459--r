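Package: ionsomatic
Title: Ensemble Strategies for Somatic SNV Identification from Ion
    Torrent Deep Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving high-confidence somatic single-nucleotide
    variants from deep targeted amplicon sequencing on flow-based (Ion
    Torrent style) platforms. Implements four caller channels (Ion
    Reporter ingestion, a tumor-normal VCF subtraction caller, a MuTect
    rejection-rescue channel, and VarScan2 somatic p-value filtering),
    population-database and functional-class exclusion filters, a
    rule-based classifier that automates visual-inspection criteria for
    homopolymer and alignment artifacts, caller-concordance and
    combination-strategy evaluation, and positive predictive value and
    sensitivity estimation with extrapolation to uninspected calls and
    binomial standard errors. A synthetic-data generator produces fully
    ground-truth-labelled fixtures (reference panel, caller VCFs, MuTect
    call-stats, annotations, read evidence) with caller-specific error
    profiles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    methods,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
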