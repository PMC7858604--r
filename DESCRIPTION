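Package: pairedEWAS
Title: Paired Epigenome-Wide Analysis of Vacation Effects on DNA Methylation
    in Shift Work Disorder
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for paired (work vs. vacation) epigenome-wide
    association studies of DNA methylation in occupational shift-work cohorts.
    Fits a group-specific ordinary-least-squares vacation-effect model per CpG
    probe, tests four nested null hypotheses (effect in the shift-work-disorder
    group, in controls, in either, and in both groups) with variance-ratio F
    tests and Benjamini-Hochberg false-discovery-rate control, classifies the
    direction of methylation change, scores pathway-level enrichment and
    hypomethylation of differentially methylated positions against GMT gene-set
    libraries, correlates methylation change with questionnaire-based recovery
    scores, and embeds global methylome profiles with t-SNE. Includes a
    synthetic 450K-style cohort simulator so that the whole pipeline is
    testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
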