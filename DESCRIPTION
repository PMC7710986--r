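Package: glbkin
Title: Ligand-Binding Kinetics of One- and Two-Heme Hexacoordinate Phytoglobins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation and inference for the ligand-binding
    kinetics of hexacoordinate plant hemoglobins (phytoglobins) with one or
    two heme domains. Builds mass-action reaction schemes for the four
    classical rapid-kinetics assays (dithionite-trap oxygen dissociation,
    laser-flash CO rebinding and O2/CO displacement, gated NO binding, and
    anaerobic nitrite reduction), integrates them as stiff ODE systems,
    generates instrument-realistic stopped-flow and flash-photolysis time
    courses and time-resolved UV-Vis spectra, and recovers rate constants
    through multi-exponential fitting with information-criterion phase
    selection, hyperbolic trap-saturation fits, second-order regression,
    concentration-independence classification, dead-time censoring bounds,
    and oxygen affinity estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    signal,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
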