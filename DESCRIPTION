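Package: fpanet
Title: Fractional Preferential Attachment Networks and Their Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates scale-free networks by fractional preferential
    attachment (FPA): Barabasi-Albert growth restricted to the top
    degree-ranked fraction f of existing nodes, with a parent-comparison
    redirection rule. Tuning f in (0,1] yields degree distributions
    p(k) ~ k^-gamma with any exponent 2 < gamma <= 3, making FPA ensembles
    useful null models for biological and other real-world networks. The
    package also provides the matching measurement suite: degree
    distribution and CCDF exponent fits, average-nearest-neighbour-degree
    (assortativity) curves and exponents, clustering, exact tree diameter
    and path length, random sequential box covering with a
    fractal/non-fractal classification, and reproducible ensemble
    experiments with derived sub-seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
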