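Package: dcmpeb
Title: Hierarchical Dynamic Causal Modelling of Fluctuating Effective
    Connectivity from Windowed Cross-Spectral EEG Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks window-to-window fluctuations in extrinsic (between-source)
    effective connectivity from resting-state EEG. A linearized ERP-style
    neural mass network model predicts channel-level complex cross-spectral
    densities; each time window is inverted with a variational-Laplace engine;
    within-subject fluctuations of the window-level log coupling gains are
    modelled by a second-level Bayesian linear model over temporal basis
    functions (discrete cosine set plus a mono-exponential decay) estimated by
    parametric empirical Bayes; Bayesian model reduction scores all
    combinations of the basis functions, evidence is pooled over subjects, and
    a third-level (group) parametric empirical Bayes with greedy pruning and
    Bayesian model averaging identifies fluctuation components conserved over
    subjects. Includes a seeded multi-subject synthetic-data generator for
    end-to-end parameter-recovery validation.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
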