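Package: crmage
Title: Guide RNA and Repair Oligo Design for CRISPR-Assisted MAGE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design toolkit for CRISPR-assisted multiplex automated genome
    engineering (CRMAGE) in bacteria. Enumerates NGG PAM sites on both
    strands within a window around a desired point edit, extracts N20
    protospacers, scores each candidate by counting genome-wide approximate
    matches (Hamming distance below a mismatch-exclusion threshold), selects
    the candidates with the fewest off-targets, and emits 80-base
    single-stranded repair templates that carry the edit together with a
    PAM-escape mutation whenever the edited locus would otherwise remain
    cleavable by Cas9. Includes a seeded synthetic-genome generator with
    planted protospacers and ground-truth off-target tables for validation,
    and utilities for two colorimetric screen readouts used with such
    experiments: colony-count killing rates and indigoidine absorbance
    indices (A615/A800).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
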