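Package: nstrat
Title: Marker-Based Survey of Microbial Nitrogen Acquisition Strategies
Version: 0.1.0
Authors@R: person("Maintainer", "nstrat", email = "nstrat@example.org",
    role = c("aut", "cre"))
Description: Detects ten nitrogen (N) acquisition strategies in microbial
    proteomes using position-specific profile models built from marker
    reference alignments, calls strategies with a monotone rule engine
    (nitrogenase NifHDK completeness, NasA/nitrite-reductase co-occurrence,
    amino-acid transporter families), applies MIMAG-style genome quality
    filters, estimates per-strategy prevalence with bootstrap medians and
    95 percent confidence intervals, and fits the association models used
    in genome-scale trait surveys: strategy-count scaling with genome size,
    Kruskal-Wallis/Wilcoxon metabolism contrasts, logistic and Poisson
    models with family-level taxonomic adjustment, Welch host contrasts,
    and linear or logistic PCA ordination of the binary strategy matrix.
    A seeded synthetic-community generator plants marker homologs with
    known effect structure so the full pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    methods,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
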