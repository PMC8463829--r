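Package: pbsplan
Title: Margin-Based and Robust Target Volumes for Proton Pencil Beam Scanning Planning Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale proton pencil-beam-scanning (PBS) planning
    studies on synthetic abdominal phantoms. Builds voxelized density phantoms
    with a gross tumor volume and abutting serial organ at risk, ray-traces
    water-equivalent thickness (WET) through a relative-stopping-power grid,
    constructs uniform and beam-specific (WET-based) optimization target
    volumes, optimizes spot weights per field under margin-based and robust
    minimax schemes with an analytic Bragg-peak dose kernel, and evaluates plan
    robustness with a 42-scenario passing rate, DVH bandwidth statistics, and a
    dose spread function (FWHM/FW20M) across the target-duodenum abutment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
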