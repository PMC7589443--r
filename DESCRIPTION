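Package: napusPheno
Title: High-Throughput Shoot Phenomics and Dynamic QTL Mapping for Rapeseed
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An image-to-QTL pipeline for greenhouse shoot phenotyping of
    Brassica napus substitution-line populations. Segments side- and top-view
    RGB images (HSI and excess-green thresholding with connected-component
    cleaning), extracts 43 dynamic image-derived traits (morphology, box-counting
    fractal dimension, grey-level histogram texture, colour, and model-based
    fresh/dry weight), fits biomass and growth-curve model catalogues, predicts
    final yield by stepwise linear regression with cross-validation, estimates
    broad-sense heritability from REML variance components, and maps dynamic QTL
    in chromosome-segment substitution lines (stepwise-background LOD scan,
    Dunnett validation against the recurrent parent, interval intersection and
    nonredundant merging, and a 1-Mb permutation hotspot test). A synthetic-data
    layer generates imaging scenes, growth series and populations with known
    ground truth so the whole stack is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    lme4,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    multcomp,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
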