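Package: dgnet
Title: Dentate Gyrus Network Simulator with Homeostatic and Hebbian Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic binary (McCulloch-Pitts) network model of the dentate
    gyrus circuitry (granule cells, mossy cells, interneurons) with
    phenomenological nonsynaptic membrane dynamics (sodium influx and Na/K-pump
    efflux), structural plasticity by the compensation theory of
    synaptogenesis, and Hebbian/anti-Hebbian rewiring.  Implements the three
    in-silico protocols used to study epileptogenesis after status
    epilepticus - rest, stimulation, and stimulation with transient excitatory
    GABAa - together with detection of spontaneous increases of cell activity
    (SICA), parameter sweeps over the plasticity gains, and summary metrics of
    activity and connectivity change.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
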