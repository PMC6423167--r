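Package: hybridclamp
Title: Desk-Scale Dynamic-Clamp Simulation of Hybrid Neuron Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clock-abstracted simulation of closed-loop dynamic-clamp
    experiments that couple a model neuron to a living (here, emulated)
    bursting neuron through model synapses. Provides a library of
    spiking-bursting neuron models (Rulkov map, Izhikevich,
    Hindmarsh-Rose, minimal conductance-based bursters), electrical,
    chemical and graded synapse models, fixed-step and embedded
    Runge-Kutta integrators, automatic amplitude and time-scale
    calibration against a target neuron, and a periodic-loop engine with
    per-operation latency accounting and overrun recovery. Experiments
    follow a control-coupled-control protocol configured from XML, and
    rhythm coordination is quantified with a circular burst-phase index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    graphics,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
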