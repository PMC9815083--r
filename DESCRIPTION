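Package: microphys
Title: Single-Cell Growth Kinetics, Dry-Mass Imaging and Microscale
    Material Balancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative single-cell physiology for microbial cells grown
    in microfluidic cultivation devices. Converts quantitative-phase images
    into single-cell dry masses, volumes and dry-mass densities; estimates
    Monod growth kinetics (maximum specific growth rate and whole-cell
    substrate affinity) from mother-machine division records using
    geometric-mean doubling times with outlier down-weighting; computes
    substrate-to-biomass yield coefficients from picoliter-batch chamber
    observations; closes the carbon material balance on a Cmol basis to
    derive specific uptake and by-product formation rates; and simulates
    ensembles of Monod batch trajectories whose substrate affinity is drawn
    from an empirical frequency distribution, mapping the physiological
    space of a heterogeneous population. A synthetic-data generator
    emulating the microfluidic experiments makes the whole pipeline
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
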