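Package: svzmeth
Title: DNA-Methylome Classification of Subventricular-Zone Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of CpG methylation signatures that
    classify IDH-wildtype glioblastoma by subventricular-zone (SVZ)
    association. Implements probe filtering and M-value preprocessing for
    450K-style beta-value matrices, differential methylation, a
    clustering-stability probe pruning step, random-forest CpG ranking and
    k-CpG signature selection, hierarchical-clustering-based SVZM
    classification, Kaplan-Meier / Cox / Weibull survival comparison,
    contingency-table and rater-agreement statistics (including Barnard's
    unconditional exact test, Goodman-Kruskal lambda and ICC), copy-number
    segmentation from methylation-array log-ratios with automatic
    gain/loss thresholds, multi-pipeline mutation-call consensus and
    enrichment, SAM-style permutation-FDR differential methylation with
    cross-cohort consensus, methylation-expression integration, and
    pathway-activity scoring. A synthetic cohort generator with planted
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    MASS,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
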