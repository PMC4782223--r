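Package: actrlocality
Title: ACT-R Retrieval Simulation and Shifted-Lognormal Analysis of
    Locality Effects in Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how working-memory capacity (WMC) modulates
    locality effects in sentence reading. Implements a simplified ACT-R
    declarative-memory retrieval model (base-level decay, spreading
    activation with cue fan, logistic activation noise, retrieval
    threshold) with three linking hypotheses that map WMC onto model
    parameters (capacity as decay rate, as source activation, or as
    susceptibility to interference), plus a modified retrieval-failure
    mechanism in which sub-threshold retrievals abort early at a uniformly
    distributed time. Provides exact closed-form locality algebra used as
    oracles for the simulator, a generator of synthetic self-paced-reading
    datasets with crossed random effects and participant-varying shifts,
    Bayesian shifted-lognormal hierarchical models of reading times fitted
    with JAGS (effect sizes, credible intervals, split R-hat, WAIC model
    comparison), and scoring of operation-span (partial-credit unit) and
    rapid-automatized-naming fluency measures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    rjags,
    coda,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
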