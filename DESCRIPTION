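Package: ampartrap
Title: Particle-Based Simulation of AMPA Receptor Diffusion and Synaptic Trapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo simulator of AMPA-type glutamate receptor lateral
    diffusion on a dendritic membrane segment with reversible trapping at
    postsynaptic densities. Receptors perform 2D Brownian motion with
    region-dependent diffusion coefficients, meet a probabilistic crossing
    barrier at synapse borders, and bind/unbind immobile scaffold with
    first-order kinetics. Ships the standard in-silico plasticity protocols
    (basal steady state, long-term potentiation as a step decrease of the
    unbinding rate, scaffold-assembly phosphorylation as an elevated binding
    rate, and a binding-rate sweep linking basal synaptic content to
    potentiation capacity), replicate management with cross-replicate
    summaries, steady-state enrichment analysis, and deterministic CSV/JSON
    serialization with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
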