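Package: fusepore
Title: Fusion Pore Conductance Analysis and a Mechanical Model of
    Calcium-Triggered Pore Dilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single fusion-pore electrophysiology and membrane
    mechanics. Simulates patch recordings of nanodisc-to-cell fusion pore
    currents (Poisson pore nucleation, exponential burst lifetimes,
    geometric flicker counts, calcium-dependent open-pore conductance),
    idealizes recordings into bursts and flickers and computes per-pore
    metrics (mean open-pore conductance, open probability, burst lifetime,
    flicker statistics, nucleation and expansion rates), converts
    conductances to pore radii with a cylindrical pore model, builds
    pore-size distributions and Boltzmann-inverted apparent free-energy
    profiles, fits Hill-equation calcium titrations, and implements a
    mechanical "lever" model of the fusion pore in which Helfrich membrane
    energetics, SNARE zippering and crowding statistical mechanics, and
    calcium-dependent reorientation of the synaptotagmin C2B domain
    jointly set the pore size distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
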