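Package: colltraits
Title: Trait-Based Analysis of Collembola Communities Across Forest Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of springtail (Collembola)
    communities sampled from layered soil cores in replicated forest-type
    designs. Implements allometric body-mass and metabolic-rate scaling and
    plot-level community metabolism, community-weighted mean trait profiles,
    vertical-stratification and trophic-guild composition metrics, functional
    evenness and divergence in a Gower trait space, individual-based
    rarefaction with Chao1 extrapolation, Bray-Curtis dissimilarity with
    PERMANOVA, multivariate dispersion and environmental vector fitting, and
    linear mixed-effects inference with treatment contrasts against a
    reference forest type. Includes a seeded generator of study-like
    synthetic data sets for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    vegan,
    lme4,
    lmerTest,
    emmeans,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
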