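Package: cocodyn
Title: Multi-Strain SIS Co-Colonization Dynamics and Its Replicator Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the N-strain susceptible-infected-susceptible (SIS)
    model with co-colonization, where strain diversity enters only through an
    N x N matrix of altered susceptibilities to co-colonization. Implements
    the similarity decomposition of the interaction matrix into a reference
    coefficient, a deviation scale and a normalized deviation matrix; the
    closed-form neutral equilibrium and its fast linearization; the pairwise
    invasion fitness network; the explicit replicator equation governing
    slow strain-frequency dynamics; reconstruction of epidemiological
    variables from frequencies; quasi-neutrality diagnostics; and validation
    of the slow-fast reduction against the full compartmental system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
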