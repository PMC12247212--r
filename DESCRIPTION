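Package: scbli
Title: Single-Cycle Kinetic Analysis of Biolayer Interferometry Sensorgrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cycle (kinetic-titration) biolayer
    interferometry experiments, in which one biosensor sequentially probes a
    series of increasing analyte concentrations. Provides closed-form
    piecewise 1:1 Langmuir binding models (standard and
    partial-dissociation variants with a global mobile fraction or
    per-step plateaus), global bounded nonlinear least-squares estimation
    of the association rate constant, dissociation rate constant and
    maximal response, degrees-of-freedom-corrected goodness of fit,
    steady-state affinity analysis, expression-level ranking from sensor
    loading traces, and a seeded synthetic-sensorgram simulator with
    Gaussian noise, linear drift and inter-step bulk shifts. Includes
    readers and writers for tidy CSV sensorgrams and YAML/JSON assay
    schedules plus command-line entry points for fitting, simulation and
    ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
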