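Package: dreamtdmr
Title: Tissue-Dependent Differentially Methylated Region Discovery from
    Methyl-Sensitive Restriction Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls tissue-dependent differentially methylated regions
    (T-DMRs) from methyl-sensitive restriction enzyme tiling-array data of
    the D-REAM type, in which fragments flanking unmethylated HpyCH4IV
    (ACGT) sites are selectively amplified and raise probe signal. The
    package fits a sequence/copy-number probe-affinity baseline, computes
    windowed trimmed-mean differential scores at restriction sites,
    calibrates per-comparison score thresholds from COBRA (combined
    bisulfite restriction analysis) validation measurements, assigns sites
    to strand-aware TSS flanking windows, classifies tissue-specific
    hypomethylated sites, and links calls to functional-category, TF-target
    and expression readouts with exact and rank-based tests. A synthetic
    data generator with recorded ground truth makes every stage testable
    without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
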