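Package: zebratox
Title: High-Throughput Zebrafish Developmental Toxicity Screening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput embryonic zebrafish
    chemical screens: binary morphology endpoint aggregation, lowest-effect-level
    and Fisher activity calls, binomial log-logistic benchmark-concentration
    (BMC/BMD10) modeling, embryonic and larval photomotor response hit rules
    built on two-sample Kolmogorov-Smirnov statistics, a negative-binomial
    differential-expression summary with UpSet-style overlap logic, and
    ToxPi-style multi-domain chemical prioritization with Ward hierarchical
    clustering. Ships a synthetic plate-data generator with known ground truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
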