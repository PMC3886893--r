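Package: netsignal
Title: Discrete-Event Simulation of Signal Traffic on Directed Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A queueing-network model of inter-regional communication on
    directed, unweighted connectomes. Signal units are generated by a Poisson
    process, routed by an unbiased random walk over directed edges, served at
    each node with exponential service times under non-preemptive LIFO
    queueing, and stored in finite push-out buffers in which an arrival at a
    full buffer ejects the oldest waiting unit. The package provides the
    event-driven simulator with full per-unit tracing; degree-preserving
    randomized and latticized surrogate generators plus ring-lattice,
    small-world and planted rich-club synthetic networks; rich-club
    coefficient profiles against degree-matched nulls with rich/feeder/local
    edge stratification; node-, edge-, network- and path-level congestion
    statistics with transient removal; an analytic steady-state model
    (absorbing random-walk traffic equations feeding finite-buffer
    single-server queue formulas) used to verify the simulator; and the
    ensemble comparison framework (Welch tests, Benjamini-Hochberg FDR,
    Fisher r-to-z scenario similarity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
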