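Package: pairnet
Title: Stimulus-Pair Selectivity and Synaptic Plasticity in Recurrent
    Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates randomly connected recurrent networks of
    conductance-based leaky integrate-and-fire neurons receiving Poisson
    input groups, and studies how synaptic plasticity rules (pair and
    triplet spike-timing-dependent plasticity, long-term potentiation of
    inhibition with spike veto, and homeostatic multiplicative scaling)
    sculpt stimulus-pair selectivity. A winner-take-all decision circuit
    with an urgency ramp and dopamine-modulated reward plasticity is
    trained on a biconditional (XOR) discrimination task over four
    stimulus pairs. Includes the stimulus-pair selectivity metric,
    decision-performance binning, group weight-change matrices,
    cross-correlograms, and a sigmoidal selectivity-performance fit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    minpack.lm,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
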