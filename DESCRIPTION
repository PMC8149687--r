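Package: beastrack
Title: B-Spline Explicit Active Contour Cell Tracking for Calcium Imaging of
    Moving Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation, tracking and signal extraction for time-lapse
    fluorescence (Ca2+) imaging of moving, contractile tissue such as the
    enteric nervous system. Cell boundaries are represented as explicit
    B-spline curves in polar coordinates (r = psi(theta)) and evolved by
    gradient descent on localized region-based (Yezzi) image energies with
    curvature, area-range, area-stability and inter-cell competition
    (proximity and overlap) regularization. A coupled double-contour mode
    tracks the dark nucleus and bright cytoplasm of GCaMP-expressing cells
    jointly, enabling cytoplasm-selective signal extraction. Tracked cell
    centroids can serve as landmarks to estimate per-frame geometric
    transforms that propagate manually drawn regions of interest. A synthetic
    scene generator produces ground-truthed benchmark recordings with
    overlapping cells, dark nuclei, motion, out-of-focus frames and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    yaml,
    jsonlite,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
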