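Package: faquant
Title: Focal Adhesion Morphometrics, Colocalization and Dynamics from
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying septin and focal
    adhesion (FA) biology in adherent cells from multi-channel fluorescence
    images and time-lapse stacks: FA segmentation (median filter, Otsu
    threshold, particle analysis with an area filter), per-adhesion
    pixel-wise Pearson colocalization split by inner (perinuclear) and
    outer (peripheral) cell regions, cross-FA line-scan profiles with
    min-max normalization and LOESS smoothing, structure-tensor anisotropy
    of filamentous bundles, kymographs and minimum-lifetime / formation-rate
    measurements, cell migration metrics (speed, persistence, forward
    progress), cell area and fibronectin clearance-per-cell assays, and the
    accompanying nonparametric statistics (Mann-Whitney U, Kruskal-Wallis
    with Dunn's post hoc, random binning). A seeded synthetic-scene
    generator provides images with complete ground truth (labels, true
    per-object correlations, lifetimes, tracks) so that every stage of the
    pipeline can be validated without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
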