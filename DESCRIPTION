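Package: polyassoc
Title: Case-Control SNP Association and Polygenic Risk Stratification
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for candidate-SNP case-control association studies and
    polygenic risk stratification. Implements Hardy-Weinberg equilibrium
    testing, contingency-table odds ratios with Woolf confidence intervals
    and Pearson chi-square p-values, genetic-model encodings (allelic,
    codominant, dominant, recessive), covariate-adjusted odds ratios via an
    in-house iteratively reweighted least squares logistic regression,
    combined-genotype (multi-SNP) risk stratification, a multiplicative
    polygenic model of variance explained with log-normal risk-percentile
    and screening-benefit arithmetic, and a synthetic case-control cohort
    generator for calibration and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
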