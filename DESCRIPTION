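Package: snakeid
Title: Crowdsourced Snake Identification Accuracy with Hierarchical Graded
    Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing crowdsourced species-identification
    challenges, motivated by online snake identification. Free-text
    identifications are resolved against a taxonomy and scored on a
    four-point ordinal scale (incorrect/skip, family, genus, species), with
    a parallel binary score for medically important venomous snake (MIVS)
    status. Identification accuracy is modelled with a hierarchical Bayesian
    graded response model: ordered thresholds on a cumulative-logit scale,
    latent participant ability, correlated difficulty and discrimination
    effects for photos and species on a log link, and fixed effects for
    snake family, photo region, participant home region and within-challenge
    learning. Includes a forward simulator with known ground truth for
    recovery testing, a gradient-based no-U-turn posterior sampler,
    Pareto-smoothed importance-sampling leave-one-out model comparison,
    Bayesian R-squared, held-out mean absolute error, and the descriptive
    summaries used in crowdsourcing studies (participant quintile accuracy,
    per-photo consensus, venomous-genus confusion tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
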