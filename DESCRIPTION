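Package: scloom
Title: Circuit Modelling and Spike-Train Analysis of Visual Sifting in the Superior Colliculus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how looming-stimulus selectivity, position
    invariance and stimulus-specific habituation arise along the depth of the
    mouse superior colliculus. Provides generators for the standard stimulus
    battery (expanding/contracting disks, dimming, moving disks, flickering
    checkerboards, random-location looming protocols); a linear-nonlinear
    cascade circuit model in which local looming detectors built from fast
    centre and slow surround Off inputs are pooled by a widefield unit through
    short-term depressing synapses; a synthetic spike-train generator driven by
    that model through inhomogeneous Poisson sampling; trial-based spike-count
    statistics (Poisson significance testing with a floored mean, selectivity
    and habituation indices, receptive-field size from gridded responses,
    first-spike latency variability, recovery curves); spike-triggered-average
    receptive-field estimation with singular-value space-time separation; and
    population decoding of stimulus location and novelty with virtual-neuron
    augmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
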