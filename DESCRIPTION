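Package: qsgrowth
Title: Resource- and Density-Limited Bacterial Growth and Death Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits coupled ordinary differential equation models
    of bacterial growth and death in a closed environment, combining Monod-type
    resource limitation with a phenomenological density-dependent (quorum-
    sensing-like) growth inhibition term and an always-active death rate.
    Provides synthetic CFU and OD time-course generators with replicate
    structure and realistic sampling schedules, exponential-phase growth- and
    death-rate estimation, multi-start bounded nonlinear least-squares fitting
    with AIC/BIC model comparison, attainable-region (feasibility) mapping of
    time-to-maximal-fold-change versus maximal fold change, and phenotype
    analyses (time-series hierarchical clustering, kinetic-parameter PCA,
    correlations, archetype distances, dispersion statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
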