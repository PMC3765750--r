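Package: bsqc
Title: Quality Assessment for Bisulfite-Treated Methylation Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality-assessment toolkit for bisulfite-treated methylation
    sequencing. Estimates bisulfite conversion rates from non-CpG cytosines
    at the chromosome and target-region level, classifies target regions by
    conversion rate and coverage against user thresholds, compares the DNA
    sequence structure (base composition, CpG density, softmasked repeat
    content) of region classes, trims FASTQ reads by fixed length or
    quality, constructs in-silico reduced-representation (MspI) target
    regions, and simulates softmasked references, per-cytosine methylation
    tables, reads and target sets with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
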