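Package: fmgap
Title: Fibroblast-Myocyte Coupling with Voltage-Gated Gap Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates electrotonic coupling between a ventricular
    cardiomyocyte and one or more cardiac fibroblasts through gap junctions
    whose conductance is either a static constant or governed by a dynamic,
    transjunctional-voltage-gated four-state (HH/HL/LH/LL) kinetic scheme for
    homotypic Cx43, homotypic Cx45 and heterotypic Cx43/Cx45 channels.
    Provides the Luo-Rudy 1991 guinea-pig ventricular myocyte, passive (RC)
    and active (MacCannell-type) fibroblast membrane models, steady-state
    conductance-voltage characterisation with modified-Boltzmann fitting,
    a 1D strand with random fibroblast insertion and conduction-velocity
    measurement, and derived metrics: action-potential morphology, the
    early/late decomposition of the gap junctional current, and sweeps of the
    dynamic-minus-static peak current difference over fibroblast density and
    coupling conductance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
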