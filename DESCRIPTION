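Package: nemakin
Title: Active Nematic Coarsening Under an Aligning Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image-analysis toolkit for the ordering kinetics of
    active nematic cell monolayers exposed to an external aligning field.
    Provides a Beris-Edwards Q-tensor continuum simulator with active stress,
    friction, field schedules and optional active torque; structure-tensor
    extraction of nematic director fields from grayscale image stacks;
    detection and tracking of half-integer topological defects with
    nearest-neighbour statistics; identification and length measurement of
    parallel and perpendicular domain-wall strings; anisotropic correlation
    functions, growth exponents and bootstrap confidence intervals; and seeded
    synthetic ground-truth generators so that every analysis stage is testable
    without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    tiff,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
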