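Package: grsbmi
Title: Unweighted Genetic Risk Scores and GRS-by-BMI Interaction Models for
    Depression Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating unweighted genetic risk
    scores (GRS) in case-control studies of depression. Implements marker
    quality control (call rate, minor allele frequency, Hardy-Weinberg exact
    test in controls, linkage-disequilibrium pruning by genotype R-squared),
    concordance-based SNP selection against literature effect directions,
    risk-allele orientation and complete-case GRS construction, nested
    logistic risk models with a GRS-by-BMI interaction term, reclassification
    metrics (NRI, category-free NRI, IDI), DeLong AUC comparisons, stratified
    k-fold cross-validation, and a synthetic-data generator that emulates the
    statistical structure of a multicentre primary-care cohort so the whole
    pipeline can be exercised without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pROC,
    caret,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
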