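Package: aortacal
Title: MRI-Informed Calibration of Lumped-Parameter Haemodynamics for
    Compliant Aortic CFD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for deriving patient-specific boundary conditions and
    wall-compliance fields for aortic computational fluid dynamics from
    routine MRI measurements. Converts brachial cuff pressures and 4D-flow
    derived flow waveforms into central pressure and outlet flow targets,
    computes vessel distensibility and compliance from cine-MRI area
    waveforms, builds and solves zero-dimensional lumped-parameter (RLC plus
    three-element Windkessel) networks of the thoracic aorta, tunes the
    Windkessel parameters iteratively against the pressure targets, and
    generates per-node stiffness and displacement fields for moving-boundary
    compliant-wall simulation. Includes a synthetic-physiology module that
    generates self-consistent virtual patients for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
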