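Package: replicomb
Title: Single-Locus DNA Replication Profiling by Molecular Combing,
    Interphase FISH and Nascent-Strand qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-locus replication profiling of large (hundreds of
    kilobases) genomic regions on stretched DNA fibers. Includes a forward
    simulator of two-pulse (IdU/CldU) labeled combed molecules with known
    ground truth (origin firing, fork rates, pauses, unidirectional forks,
    dormant intragenic origins), molecule orientation against a multi-probe
    FISH template, rule-based classification of labeled tracks into
    replication events, replication-profile summary statistics (fork rate,
    inter-origin distance, unidirectional fork lengths), replication-timing
    statistics from interphase FISH of FACS-sorted S-phase fractions, and
    quantification and normalization of short-nascent-strand qPCR enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
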