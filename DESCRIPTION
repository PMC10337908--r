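Package: nucmech
Title: Mechano-Node-Pore Sensing and Nuclear-Envelope Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for oocyte nuclear mechanics. Processes
    mechano-node-pore-sensing (mechano-NPS) current-vs-time traces into
    per-nucleus diameter, applied strain and a whole-cell deformability
    index (wCDI); quantifies nuclear-envelope fluorescence (ring intensity,
    clustering index, angular polarization profiles, patch tracking,
    collapse dynamics); scores germline gonads by equal-length zones
    (collapse, pairing, synapsis fractions); and provides the statistical
    procedures used alongside (Welch ANOVA, Games-Howell post hoc tests,
    Benjamini-Hochberg adjustment, proportion comparisons, power analysis).
    Every stage is driven by seeded synthetic-data generators with known
    ground truth, so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    data.table,
    jsonlite,
    tiff,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
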