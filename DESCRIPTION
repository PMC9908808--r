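Package: promotermine
Title: Constitutive Promoter Mining and Strength Quantification from
    Condition-Ranked Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for mining constitutive promoters in the
    oleaginous yeast Rhodosporidium toruloides from condition-wise expression
    rankings. Ranks genes per (medium, growth-phase) condition, merges top-N
    lists into a deduplicated candidate set, extracts strand-aware upstream
    promoter regions anchored at the translational start codon, scans for core
    promoter elements (CAAT motif, GC box, pyrimidine-rich CT box) and cryptic
    splice-site risk at the promoter-reporter junction, converts plate-reader
    fluorescence/OD600 wells into blank-subtracted per-cell promoter strengths
    relative to a reference promoter, and selects combinatorial promoter pairs
    for a two-gene fatty-acid desaturase pathway. Ships a seeded synthetic-data
    generator emulating the statistical structure of the study's genome,
    transcriptome, plate-reader, titer, and mixed-sugar fermentation data so
    the full pipeline is exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
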