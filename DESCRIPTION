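Package: driftmapr
Title: Mapping Coastal Driftwood Deposits from Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for mapping stranded driftwood
    deposits along Arctic coastlines from multi-temporal multispectral imagery.
    Provides a synthetic-scene simulator with known ground truth (deposit
    polygons, water persistence, catchments, river mouths, infrastructure),
    medoid compositing with histogram matching, a compact dilated U-Net
    segmentation model trained with Tversky loss, multi-year probability fusion
    into stable deposits with water/infrastructure/hole filtering, hexagonal-grid
    hotspot statistics (global and local Moran's I with permutation inference),
    nonparametric and Bayesian group comparisons and correlations, catchment
    assignment and distance-decay analysis, and evaluation of coarse-resolution
    predictions against a high-resolution reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
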