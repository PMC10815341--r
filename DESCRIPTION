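Package: tensiomap
Title: FRET Tension Mapping, Cell-Sheet Morphometry and Stretch-Response
    Expression Statistics for Embryonic Axial Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mechanical tension and its transcriptional readout in
    embryonic axial tissues. Converts two-channel (donor/acceptor) tension-sensor
    images into background-corrected FRET ratio maps and mask-normalized
    anteroposterior gradient profiles with control comparisons and
    expression-independence diagnostics; measures tissue and cell deformation
    from tracked cell polygons (equivalent-ellipse eccentricity, displacement
    order parameter, integral-ROI axis changes, apical area indices,
    Mann-Whitney start/end comparisons); and implements the expression-side
    statistics (five-group single-cell read percentages, dilution-series qPCR
    efficiency, dual-reference delta-delta-Ct fold changes, differential
    expression candidate filtering). A seeded synthetic-embryo generator
    produces every input with known ground truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tibble,
    jsonlite,
    tiff,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
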