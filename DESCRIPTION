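Package: grsnbc
Title: Genetic Risk Scores and Naive Bayes Classifiers for Case-Control
    Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of genetic risk prediction models
    for a dichotomous trait from biallelic SNP genotypes. Implements three
    genetic risk score (GRS) weighting schemes (risk-allele counting,
    additive log-odds-ratio weights, genotypic log-odds-ratio weights), the
    Naive Bayes classifier (NBC) posterior score under conditional
    independence of SNPs given the trait, and the closed-form threshold
    mappings that make the corresponding classification rules equivalent.
    Includes a case-control genotype simulator (Hardy-Weinberg null SNPs
    plus odds-ratio-tilted causal SNPs under additive, recessive and
    dominant inheritance), SNP ranking by genotypic association evidence,
    and nested-model AUC experiments with independent discovery and
    replication sets.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
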