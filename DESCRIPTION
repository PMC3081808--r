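Package: grncompete
Title: Eco-Evolutionary Competition Between Species with Boolean Gene-Network Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Forward-time, individual-based simulation of two competing species
    whose quantitative traits are encoded by heritable Boolean gene-regulatory
    networks of differing size, topology, recombination rate and mutation rate.
    Populations evolve under Gaussian stabilizing selection toward a moving
    environmental optimum; competition occurs through a shared carrying
    capacity. Includes emergent quantitative-genetic summaries (mid-parent
    heritability, additive genetic variance), factorial experiment drivers with
    reproducible seeding, and the downstream statistics used to characterise
    the adaptation speed-versus-accuracy tradeoff: sequential ANOVA
    percent-variance tables, binomial GLM analysis of deviance for competition
    winners, log time-to-resolution models, and AIC model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
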