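Package: genrisksim
Title: Simulating Genetic Risk Prediction Studies from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs individual-level genotype and disease-status data for
    hypothetical cohorts from published per-allele odds ratios, risk-allele
    frequencies and a population disease risk, and estimates the discriminative
    ability (AUC) of genetic risk models built on those data. Genotypes are
    drawn under Hardy-Weinberg equilibrium and linkage equilibrium; individual
    disease risks follow from Bayes' theorem with genotype likelihood ratios
    under a multiplicative (log-additive) per-allele model; disease status is
    assigned by comparing each risk to a uniform draw. Supports unweighted
    allele-count scores, log-odds-weighted scores and naive-Bayes posterior
    risks; nonparametric (Mann-Whitney) AUC estimation; an exact enumeration
    oracle for small panels; a replication protocol that repeats each
    simulation with odds ratios fixed at their point estimates or redrawn from
    their 95% confidence intervals; and the four standard prediction-study
    plots (risk-allele histogram, ROC curve, quintile odds ratios, risk
    vs. allele-count scatter).
License: MIT
Encoding: UTF-8
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
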