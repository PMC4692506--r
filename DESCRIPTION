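Package: mdrpipe
Title: Multifactor Dimensionality Reduction for Candidate-Gene
    Interaction Analysis in Case-Control Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting gene-gene interactions in
    case-control candidate-gene studies: Hardy-Weinberg and single-locus
    chi-square association testing with Bonferroni correction, a
    from-scratch multifactor dimensionality reduction (MDR) engine with
    stratified cross-validation, sign and permutation tests,
    high/low-risk genotype-combination recoding, and covariate-adjusted
    logistic odds ratios. Includes a seeded synthetic case-control
    cohort generator with Hardy-Weinberg genotypes, realistic covariate
    structure and a planted two-locus interaction, so every stage of the
    analysis is verifiable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
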