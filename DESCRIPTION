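Package: dcnsim
Title: Simulation of Purkinje Cell to Deep Cerebellar Nucleus Rate Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates communication between cerebellar Purkinje cells and
    deep cerebellar nucleus (DCN) projection neurons. Purkinje cells are
    modelled as independent Bernoulli spike generators sharing a synchronized
    time-varying discharge probability; each spike transfers a stereotyped
    unit quantum of inhibitory charge that decays exponentially and sums
    linearly. The package provides convergence-ratio noise-reduction
    statistics, somatic charge-entry traces with rolling-mean integration,
    random-sample wiring of a nuclear group with synchrony metrics, binomial
    analytics of recurrent collateral wiring, and an analytic plus numeric
    treatment of the phase shift produced when short-term synaptic plasticity
    adds a rate-derivative term to the afferent rate signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
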