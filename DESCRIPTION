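Package: dominet
Title: Dominance Hierarchies and Quantitative Plant-Hummingbird Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links behavioral dominance hierarchies of hummingbirds to the
    structure of quantitative plant-hummingbird visitation networks.
    Implements David's score and dominance-certainty ranking from sparse
    agonistic win/loss matrices, Kullback-Leibler species-level
    specialization (d'), Barber weighted bipartite modularity maximized by
    the DIRTLPAwb+ label-propagation algorithm with Patefield fixed-margins
    null models and z-scores, core-periphery decomposition (CPness), a
    negative-binomial generalized additive model of pairwise interaction
    frequency from traits and abundances, principal component analyses and
    linear regressions of specialization on dominance and bill morphology,
    plus seeded synthetic-data generators for tournaments, visitation
    matrices and trait tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
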