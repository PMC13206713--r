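Package: choromap
Title: High-Density Topographic Mapping of Choroidal Vascularity from OCT Macular Cubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies choroidal thickness (CT), luminal area (LA), stromal
    area (SA) and the choroidal vascularity index (CVI = LA / (LA + SA)) from
    optical coherence tomography (OCT) macular cube volumes on a fovea-centred
    60 x 60 grid spanning 7200 x 7200 micrometers. B-scans are binarized into
    vessel lumen and stroma by multiscale median-cut quantization, retinal
    vessel shadow columns are detected and excluded, and per-cell metrics are
    compared between groups with symmetric percent-change difference maps,
    ETDRS and eccentricity spatial templates, nonparametric statistics, and
    linear/quadratic eccentricity regression models. A synthetic macular-cube
    generator with per-pixel ground truth makes every stage verifiable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
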