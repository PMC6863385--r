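Package: ribopause
Title: P-Site Calibration, Trimmed Metagenes, and Polyproline Pause
    Scoring for Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the post-alignment analysis of ribosome profiling
    (Ribo-seq) libraries: read-length-specific P-site offset calibration
    from start-codon metagenes, codon-resolution P-site coverage,
    landmark-anchored metagene profiles with zero-read-transcript
    exclusion and per-position 0.1 percent outlier trimming, tripeptide
    motif (e.g. polyproline) pause scoring with bootstrap condition
    comparison, and spike-in based cross-library normalization. A
    synthetic footprint simulator with a full per-read truth table turns
    the qualitative hallmarks of eIF5A-dependent translation (start-codon
    accumulation, triproline stalling, read loss through no-go decay)
    into parameter-recovery experiments, and a preprocessing layer
    (adapter trimming, quality filtering, contaminant depletion,
    exact-match transcriptome alignment) connects FASTQ input to the
    analysis with complete read bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
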