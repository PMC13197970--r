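Package: posticu
Title: Post-ICU Care Trajectories: Sequence Clustering, Competing Risks, and Bayesian Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 90-day post-discharge care trajectories of ICU
    survivors. Builds weekly acuity-ranked state sequences from dated care events,
    clusters them with a frequency-weighted partitioning-around-medoids algorithm on
    longest-common-subsequence distances, fits Fine-Gray subdistribution-hazard and
    cause-specific Cox models with marginal standardization to adjusted absolute
    risks, and performs Bayesian counterfactual mediation of readmission risk
    through early primary-care follow-up using linked Bernoulli models with
    facility random intercepts. Includes a seeded synthetic cohort generator that
    emulates the covariate structure, latent trajectory mixture and embedded
    mediation structure the analyses assume, so the full pipeline is testable
    without access to restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    cmprsk,
    jsonlite,
    knitr,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
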