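Package: phenosink
Title: Carbon Source-Sink Manipulation Analysis for Autumn Leaf Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for randomized-block defoliation (carbon
    source-sink manipulation) experiments on deciduous saplings. Generates
    synthetic experiments with known-truth treatment effects, applies the
    documented quality-control rules to leaf gas-exchange records, derives
    whole-plant senescence metrics (inverted relative SPAD index, day of year
    of 50% senescence by threshold interpolation, trapezoidal area under the
    net-photosynthesis curve, relative organ counts), and fits linear
    mixed-effects models with Type-II Wald tests, marginal/conditional R2 and
    model-based parametric bootstrap confidence intervals. A parameter-recovery
    harness closes the loop from simulation truth to fitted effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
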