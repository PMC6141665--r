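Package: glycoPAP
Title: Quantification of Perisynaptic Astrocytic Glycogen from Volume
    Electron Microscopy Annotations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying glycogen granules in perisynaptic
    astrocytic processes (PAPs) from annotated serial block-face
    scanning electron microscopy volumes. Starting from per-ROI ball
    annotations (granule centers and diameters), astrocytic volumes and
    triangulated axon-spine-interface (ASI) meshes, the package computes
    normalized granule densities, granule diameters, estimated glucose
    residues per granule, granule-to-ASI nearest-vertex distances with a
    configurable inclusion window, and astrocytic coverage of the ASI
    perimeter, and compares them across experimental conditions with
    tie-corrected rank statistics (Kruskal-Wallis, Dunn's post hoc test,
    Spearman correlation). A seeded synthetic-study generator produces
    datasets with the same structure and calibrated summary statistics,
    so the whole pipeline is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'io.R'
    'methods-accessors.R'
    'metrics.R'
    'stats.R'
    'pipeline.R'
    'synthetic.R'
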