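Package: cellhop
Title: Nanoparticle Transport in Topologically Defined Macromolecular Network Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the topology of a macromolecular network cell
    controls the transport of a hard spherical nanoparticle trapped inside it.
    Builds polyhedral network cells (tetrahedron through truncated icosahedron)
    and their characteristic radii, evaluates the free-energy landscape of a
    nanoparticle in a Gaussian-chain network by constrained saddle-point
    relaxation with Brownian-bridge confinement entropy, cross-checks it with
    Wang-Landau flat-histogram Monte Carlo on bead-spring realizations, runs
    underdamped Langevin (NLE) dynamics on the periodized minimum-energy-path
    landscape, and provides the regime-resolved analytic mean-squared
    displacement theory with oscillation-mode classification, exponent fits,
    barrier scans and master-curve collapses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
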