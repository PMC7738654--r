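Package: nCounterFFPE
Title: Expression Analysis of Degraded FFPE RNA on the NanoString nCounter Platform
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for multiplexed gene-expression analysis of
    degraded formalin-fixed paraffin-embedded (FFPE) RNA profiled on the NanoString
    nCounter platform. Reads and writes RCC lane files, estimates per-sample
    background from negative-control probes (mean + 2 SD), screens and ranks
    housekeeping genes by geNorm stability and pairwise correlation, normalizes
    counts against a housekeeping panel, filters genes by signal-to-noise ratio
    against each sample's own background, calls differentially expressed genes by
    unpaired t-tests with a signed fold-change convention, performs exact
    hypergeometric over-representation analysis against GMT gene-set collections,
    and produces hierarchical-clustering and volcano-plot tables. Includes a
    negative-binomial synthetic-data generator that emulates degraded FFPE count
    data with known ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, ape, fgsea, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Normalization, QualityControl, DifferentialExpression
RoxygenNote: 7.3.3
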