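Package: nbdispbench
Title: Simulation Benchmark for Negative-Binomial Dispersion Estimation in RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare negative-binomial dispersion estimators for RNA-seq
    count data by simulation. Provides a pseudo-dataset generator with empirical
    mean-dispersion coupling and block-correlated differential expression, ten
    dispersion estimators spanning five shrinkage philosophies (genewise
    quasi-likelihood and method-of-moments, common and weighted-tagwise
    quantile-adjusted conditional maximum likelihood, Cox-Reid adjusted profile
    likelihood in common/trended/tagwise variants, trended and maximum
    method-of-moments, and an empirical-Bayes posterior mode under a log-normal
    prior), negative-binomial exact tests and a quasi-likelihood F-test family
    for differential expression, and evaluation by mean squared error of
    transformed dispersions and partial area under the ROC curve.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, splines, tools, yaml
Suggests: testthat (>= 3.0.0), withr, DESeq2, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
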