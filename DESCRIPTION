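Package: thermolipase
Title: Screening and Thermal Deactivation Kinetics of Thermophilic Lipases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial lipase bioprospecting data:
    dual-mode (agar halo / liquid culture) screening classification and
    selection of lipolytic strains, conversion of p-nitrophenyl palmitate
    assay absorbances to nanokatal activities, two-step series thermal
    deactivation kinetics (native -> partially active intermediate ->
    inactive) fitted by constrained nonlinear least squares with multistart,
    Arrhenius activation-energy estimation for the deactivation rate
    constants, pH/temperature activity-profile summaries, and a synthetic
    data generator that emulates the statistical structure of the assays so
    the whole pipeline is testable without laboratory data. Ships the
    screening table and fitted deactivation parameters of a 101-strain
    collection of thermophilic isolates from the Santorini volcanic habitat.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
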