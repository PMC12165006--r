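Package: netspill
Title: Spillover Effects of Treatment in Risk Networks via Community-Level
    Inverse Probability Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates direct, spillover, total, and overall effects of a
    binary treatment on a binary outcome among participants of an undirected
    risk network under partial interference. Interference sets are defined by
    modularity-based community detection (greedy agglomeration and leading
    eigenvector); confounding is adjusted with community-level propensity
    scores obtained by integrating a mixed-effects logit over a normal
    community random intercept (adaptive Gauss-Hermite quadrature), and
    effects are estimated by inverse probability weighting under Bernoulli
    allocation strategies with M-estimation sandwich standard errors.
    Includes variation-of-information perturbation analysis of the
    significance of community structure against degree-matched null
    networks, random-forest covariate imputation, mixed-logit and
    best/worst-case outcome imputation, extreme-weight sensitivity
    analysis, and a synthetic study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    randomForest,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    lme4,
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
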