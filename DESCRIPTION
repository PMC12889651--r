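Package: ctmd
Title: Binding-Pose Stability Ranking from Short Well-Tempered
    Metadynamics Runs via the c(t) Reversible-Work Estimator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks ligand binding-pose stability by the lowest terminal
    value of the reversible-work estimator c(t) computed across a few
    short, independent well-tempered metadynamics replicas (the CTMD
    protocol), together with the early-enrichment evaluation toolkit
    used to benchmark virtual-screening triage: enrichment factors at a
    selection threshold, BEDROC, pKi-based binder labeling, and binder
    subsampling with replacement. Includes overdamped Langevin dynamics
    on analytic one-dimensional model potentials, a well-tempered hill
    deposition engine, PLUMED-style HILLS file input/output, and a
    synthetic-screen generator so the full pipeline runs end-to-end
    with no molecular dynamics package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
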