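Package: hygrex
Title: Coupled Gravimetric and Imaging Analysis of Wood Sorption and
    Hygroexpansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simultaneous tracking of wood mass and in-plane
    dimensions during water-vapour sorption experiments. Implements CIELAB
    threshold segmentation of time-lapse specimen images, mask cleanup
    (artifact removal, hole filling, rotation alignment), centre-band width
    estimation, moisture-content and equilibrium-criterion logic for
    stepwise humidity schedules, and derived sorption and swelling
    statistics (isotherms, hysteresis, differential swelling, normalized
    step dynamics, time to approximate equilibrium). A synthetic virtual
    instrument generates ground-truthed mass logs, dimension series and
    rendered specimen frames so the whole pipeline is testable without
    laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
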