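Package: sarcoquant
Title: Quantification of Sarcomere Ultrastructure and Mechanics Under Graded Titin Cleavage
Version: 0.1.0
Authors@R: person("Sarcoquant", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for experiments that cleave the elastic
    I-band region of titin in permeabilized muscle fibers and measure the
    structural and mechanical consequences. Implements a Z-disk disorder
    ("fracture area") metric from electron micrographs via orthogonal
    regression of segmented Z-disk lines, immunogold particle detection and
    epitope-to-Z-disk distance mapping, passive ramp-hold viscoelastic
    decomposition and active force analysis, Hertz spherical-indenter
    fitting of AFM nanoindentation curves, titin gel lane densitometry, and
    an order-of-magnitude thick-filament centering force balance. A
    synthetic-data module generates ground-truth-labeled micrographs,
    particle fields, force traces, indentation curves and gel lanes so
    every stage is testable without raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
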