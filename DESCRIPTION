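Package: traitnets
Title: Genomic and Residual Trait Networks from Multivariate Kinship Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers separate genomic and residual trait networks for
    multi-trait panels of inbred (doubled-haploid) lines. Phenotypes are
    decomposed with a Bayesian multivariate kinship model fitted by Gibbs
    sampling, the genomic component is decorrelated across genotypes via the
    Cholesky factor of the kinship matrix, Gaussian Bayesian-network
    structures are learned from both components with constraint-based
    (Grow-Shrink) and score-based (tabu search, BIC/BGe) algorithms under
    bootstrap arc-strength averaging, and the learned structures are ranked
    by embedding them in recursive structural equation models assessed with
    DIC, a plug-in marginal likelihood, and replicated cross-validated
    predictive ability. A synthetic-data generator with known sparse network
    truths makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
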