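Package: vertexcomp
Title: Vertex-Model Simulation of Mechanical Cell Competition in Epithelia
Version: 0.1.0
Authors@R: person("vertexcomp", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A 2D vertex-dynamics model of epithelial tissue in which an
    abnormal cell population grows inside a normal one and elevated
    actomyosin contractility acts on the interface between the two. The
    package simulates the full dynamics (energy gradient descent, T1 edge
    reconnection, T2 cell elimination, clock-driven cell division) and
    implements the accompanying closed-form theory: the hexagonal ground
    state and its elastic moduli, the cluster-level force-balance cubic
    with its saddle-node bifurcation, the two critical densities for
    mechanical elimination (homeostatic and population-stability), and the
    Laplace scaling of the elimination phase diagram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
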