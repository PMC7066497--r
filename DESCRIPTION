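Package: dbsnet
Title: Population-Level Model of the Basal Ganglia-Thalamocortical Network
    Under Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a Wilson-Cowan firing-rate model of the combined
    cerebellar-basal-ganglia-thalamocortical circuit (cortex, thalamus,
    thalamic reticular nucleus, deep cerebellar nuclei, external and
    internal globus pallidus, and subthalamic nucleus) and the effect of
    deep brain stimulation (DBS), delivered as a truncated Fourier-series
    square wave into a chosen target population.  Provides deterministic
    integration of the seven coupled population equations with a compiled
    right-hand side, Welch power-spectrum analysis with dominant-frequency
    extraction and oscillation-state classification (tremor, beta, gamma,
    entrained, suppressed), phase-lead ordering of populations, and an
    experiment battery: named parameter presets for gamma/tremor/beta
    regimes, random parameter surveys, single and pairwise parameter
    sweeps, DBS amplitude and frequency sweeps, and grid-search threshold
    location.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
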