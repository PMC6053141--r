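Package: grsmiss
Title: Simulating the Impact of Missing SNPs on Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of weighted and unweighted genetic risk
    scores (GRS) for a binary phenotype when a fraction of the score's SNPs is
    unavailable in the target sample. Generates synthetic genotype panels in
    Hardy-Weinberg equilibrium with proxy SNPs at controlled linkage-
    disequilibrium tiers, simulates phenotypes from a logistic causal model
    calibrated to a target prevalence, and compares the omission and
    proxy-replacement strategies against the gold-standard score in terms of
    odds ratio per standard deviation, statistical power, area under the ROC
    curve, and correlation with the gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    pROC,
    optparse
Config/testthat/edition: 3
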