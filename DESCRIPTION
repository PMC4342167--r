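Package: ngvmet
Title: Multi-Timescale Simulation of Neuron-Glia-Vasculature Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates activity-dependent metabolic coupling in the
    neuron-astrocyte-vasculature ensemble with a stiff system of 33 ordinary
    differential equations joining Hodgkin-Huxley membrane excitability,
    compartmentalized energy metabolism with cytosolic and mitochondrial NADH,
    reversible carrier transport of glucose, lactate and oxygen, and
    Balloon-model hemodynamics. Provides scenario generators for in vitro and
    in vivo (rodent, human) stimulation protocols, steady-state solving with
    Jacobian stability analysis, derived observables (tissue NADH and lactate
    transients, CMRglc, CMRO2, oxygen-glucose index, BOLD), two-tier parameter
    calibration (algebraic steady-state constraints plus Nelder-Mead fitting
    to NADH reference curves), and a synthetic NADH reference-curve generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
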