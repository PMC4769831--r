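Package: rrbspipe
Title: Targeted Alignment and Methylation Calling for Reduced
    Representation Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns directional reduced representation bisulfite sequencing
    (RRBS) reads to an in-silico MspI-digested, end-repaired,
    adapter-annealed fragment reference instead of the whole genome, and
    calls CpG methylation while excluding the artificial cytosines
    incorporated during end repair. Includes a read simulator with per-CpG
    methylation truth tables, evaluation metrics (alignment accuracy,
    recall, R-squared against truth, methylation autocorrelation, fragment
    uniqueness), and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
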