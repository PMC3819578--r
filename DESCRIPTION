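Package: petbbt
Title: Blood-Brain Transfer Kinetics of PET Tracers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies unidirectional blood-brain transfer of dynamic PET
    tracers. Implements multitime graphical analysis (Gjedde-Patlak)
    estimation of the unidirectional clearance K1 from regional
    time-activity curves and arterial input functions, cerebral blood flow
    estimation from [15O]water sessions via a linearized one-tissue
    compartment model solved by non-negative least squares, and conversion
    of (K1, F) pairs to extraction fractions and permeability-surface area
    products through the Crone-Renkin relations. Includes a synthetic-data
    module that simulates arterial input functions with metabolite (parent
    fraction) correction, one-tissue tissue kinetics, and two-group
    subject cohorts, plus a pipeline producing group summary tables with
    between-group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
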