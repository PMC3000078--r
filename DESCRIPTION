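Package: calorikin
Title: Kinetic Analysis of Irreversible Thermal Denaturation from DSC Thermograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing differential scanning calorimetry (DSC)
    thermograms of multidomain proteins that denature irreversibly under
    first-order (Arrhenius) kinetics.  Provides forward simulation of
    one-stage and two-stage (N -> I -> D) calorimetric domains under
    constant-rate heating or isothermal holds, the W(T) diagnostic and a
    recursive peeling procedure for estimating activation energies and
    special temperatures from excess heat-capacity curves, design of
    annealing (pre-incubation) schedules that selectively erase less
    stable transitions, iterative chemical-baseline correction, and joint
    nonlinear fitting of native plus annealed thermogram sets.  Companion
    modules fit isothermal aggregate-growth traces from dynamic light
    scattering, intrinsic-fluorescence spectral parameters, and
    first-order enzyme-inactivation time courses, and a seeded synthetic
    data generator supplies every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
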