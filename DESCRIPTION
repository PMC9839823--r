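Package: rdgrow
Title: Reaction-Diffusion Pattern Formation on Concentration-Dependent
    Evolving Domains
Version: 0.1.0
Authors@R:
    person("rdgrow", "developers", email = "rdgrow@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of reaction-diffusion systems on
    domains whose growth and contraction are driven by the morphogen
    concentrations themselves. Provides a library of classical kinetics
    (Schnakenberg, Gierer-Meinhardt, FitzHugh-Nagumo, logistic, bistable)
    and concentration-dependent growth laws; a closed one-dimensional
    Lagrangian solver with a compiled adaptive stiff integrator, epoch-based
    remeshing and kymograph diagnostics; linear instability analysis about
    spatially homogeneous evolving base states, including per-mode
    instability intervals and direct mode-amplitude integration; and a
    planar two-dimensional moving-mesh solver in which the domain evolves
    by an irrotational potential flow obtained from a finite-element
    Poisson solve. Configuration documents, figure presets and CSV/JSON
    result serialization are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
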