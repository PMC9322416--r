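Package: egpvar
Title: Variance Decomposition of Reproductive Success via Extra-Group
    Paternity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions the variance in male lifetime reproductive success
    into extra-group and within-group paternity (co)variance components,
    at the lifetime level and across age classes (zero-padded additive and
    survivor-only conventions), with mean standardization to quantify the
    opportunity for selection. Includes bias-corrected accelerated (BCa)
    nonparametric bootstrap confidence intervals resampling whole males, a
    mate-number/fecundity/paternity-share decomposition, and a calibrated
    individual-based simulator of male life histories so the full pipeline
    is reproducible without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
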