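Package: nucretain
Title: Sperm Nucleosome Retention Predicted from Fine-Scale Base Composition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed GC/CpG composition tracks, MNase-seq nucleosome
    retention scoring against a genomic input control, enrichment-region
    calling, ROC evaluation of base composition as a classifier of
    retention, gene-class retention statistics with trend tests,
    TSS-anchored meta-profiles, and the association between sperm
    nucleosome retention at CpG islands and embryonic DNA-methylation-free
    regions. Includes a synthetic genome and read simulator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
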