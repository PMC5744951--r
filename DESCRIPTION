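Package: oncotx
Title: Differential Transcript Calling, Stage-Profile Correlation and
    Pathway Activation Scoring for Two-Group RNA-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transcript-level analysis of two-group (treatment
    versus control) bulk RNA-seq experiments: Welch unequal-variances
    differential-expression calling with categorical switched-on/off
    labelling of group-specific zeros, p-value-weighted Pearson
    correlation of group-average expression profiles against a staged
    tumour reference compendium, and OncoFinder-style Pathway Activation
    Strength (PAS) scoring from activator/repressor gene role tables.
    Includes RPKM and TPM normalization, sample correlation matrices,
    classical multidimensional scaling, a synthetic-data generator with
    known ground truth for end-to-end validation, and a reproducible
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
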