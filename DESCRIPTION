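Package: plasmawell
Title: Equivalent-Circuit Network Model of Electrical Exposure in Plasma
    Gene Transfection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and solves a three-layer axisymmetric equivalent-circuit
    network of a plasma-exposed 96-well culture well (TE/PBS buffer solution,
    adherent cell monolayer with explicit membrane layers, polystyrene plate)
    by complex-phasor nodal analysis, and post-processes the solution into
    radial profiles of electric field, current density, transmembrane voltage
    and per-cell current with physiological reference bands.  Also provides a
    finite-difference electro-quasistatic solver for the uniform-medium
    comparison model, SPICE netlist export with round-trip reading,
    least-squares overlay scaling of model profiles against transfection
    efficiency data, and a synthetic efficiency-profile generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
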