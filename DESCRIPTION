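Package: knotgo
Title: Coarse-Grained Go-Model Monte Carlo Folding Simulations of Knotted Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A C-alpha structure-based (Go-type) Monte Carlo folding simulator
    for knotted and unknotted proteins. Implements a chirality-augmented native
    contact potential on a rigid-stick bead chain, crankshaft and pivot moves in
    linear-topology-preserving (LTyP) and non-preserving variants, Metropolis
    replica-exchange sampling over a temperature ladder, KMT chain reduction
    with Alexander-polynomial knot typing and knotted-core mapping, and weighted
    histogram (WHAM) estimation of thermodynamic observables: internal energy,
    heat capacity, melting temperature, folding cooperativity (FWHM/Tm), and
    knotting probability profiles along temperature and the fraction of native
    contacts Q.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
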