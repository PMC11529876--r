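Package: emmosaic
Title: Stitching, Artifact Correction and Deep Zoom Atlases for Electron
    Microscopy Montages
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Assembles overlapping electron-microscopy tile images into a
    single mosaic and publishes it as a zoomable web atlas.  Tiles acquired
    on a regular grid with roughly 30 percent overlap are flat-field
    corrected (rolling-ball, polynomial or frequency-domain high-pass),
    registered pairwise by windowed phase correlation with sub-pixel
    refinement, and placed by a weighted linear least-squares solve of the
    whole montage (translation-only model).  Tiles are projected onto the
    canvas with irregular, feathered seams so that no straight seam lines
    or brightness steps remain, the mosaic is cut into a Deep Zoom (dzi)
    image tile pyramid, and static HTML pages with a calibrated floating
    scalebar, side-by-side comparison containers and switchable colored
    overlays are generated.  A deterministic synthetic-montage generator
    with known ground truth makes every stage testable without real
    micrographs.  Grayscale PNG and baseline TIFF readers and writers are
    built in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
SystemRequirements: zlib
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
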