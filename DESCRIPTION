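Package: lethaldyn
Title: Death-Rate Inference for Drug Response Assays and Pooled CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies drug-induced cell death from plate-reader viability
    kinetics and pooled CRISPR chemo-genetic screens. Implements death-specific
    response metrics (lethal fraction, fractional viability, GR values), lag-
    exponential death kinetic fits, four-parameter logistic dose-response fits,
    and GRADE growth/death coordination scores; a biphasic growth-then-death
    population simulator; non-targeting-anchored screen count normalization
    and empirical-null significance testing; and inversion of the population
    forward model to recover per-gene drug-induced death rates (L2DR) that are
    not confounded by growth-rate variation among knockout clones. Includes a
    ground-truthed synthetic screen generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
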