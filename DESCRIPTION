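Package: p53pathtype
Title: Somatic Alteration Profiling and p53 Pathway Subtyping for Ovarian Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the multi-stage genomic characterization of
    high-grade serous ovarian cancer cohorts from paired tumor-normal data:
    heuristic somatic point-mutation calling from allele read counts with an
    exact-test filter, functional-impact classification and a permutation scan
    for driver genes, hidden-Markov segmentation of SNP-array log R ratio and
    B-allele frequency tracks into integer copy-number states, case-control
    detection of recurrent copy-number regions, allele-specific grid-search
    estimation of tumor purity, a rule-based p53-pathway-integrity subtype
    (ST1/ST2) classifier, subtype burden comparisons with exact rank tests and
    false discovery rate control (Benjamini-Hochberg and Storey), percentile-
    shift normalization and differential expression of probe-level microarray
    signals, and DAVID-style functional annotation clustering with EASE scores
    and kappa term similarity. A fully ground-truthed synthetic cohort
    generator with configurable purity, depth, mutation burden, and expression
    structure supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
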