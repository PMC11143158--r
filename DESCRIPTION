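Package: gridscape
Title: Grid-Cell Firing Fields from Place-Cell Reference Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates hexagonal grid-cell firing fields by expressing
    positions from a random-walk trajectory in place-cell local reference
    frames and linearly transforming them into a cell-specific lattice
    ("cognitive") space, where integer coordinates are preferred firing
    positions. Provides seedable random-walk trajectory generation in
    bounded single- and multi-compartment arenas, occupancy-normalized
    rate maps, estimation of lattice spacing, orientation and phase from
    simulated fields, and experience-dependent adjustment of compartment
    reference frames in connected environments, quantified by a Pearson
    correlation of global fit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
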