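Package: doxcycle
Title: Kinetic Modelling of Doxorubicin Bioactivation and Redox Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action kinetic models of the doxorubicin bioactivation
    network: cell-free (in vitro) redox cycling and reductive conversion of
    the quinone drug by cytochrome P450 reductase and NADPH, and cell-based
    (in vivo) models for doxorubicin-resistant and -sensitive acute
    lymphoblastic leukemia lines that add NADPH oxidase, superoxide
    dismutase, glucose-6-phosphate dehydrogenase and membrane transport.
    Provides stiff ODE simulation of the networks, least-squares time-course
    estimation of single rate constants, time-integrated reaction fluxes,
    local sensitivity analysis, in silico enzyme-inhibition interventions,
    and seeded synthetic-data generation for parameter recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
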