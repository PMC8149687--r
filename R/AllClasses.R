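#' PolarContour: explicit closed boundary r = psi(theta)
#'
#' An explicit closed 2D boundary represented in polar coordinates about a
#' movable pole: the radius is a periodic uniform B-spline function of the
#' polar angle, \eqn{r(\theta) = \sum_k c[k]\,\beta^d(\theta/h - k)} with
#' N regularly spaced nodes (\eqn{h = d\theta = 2\pi/N}).  Pixel coordinates
#' are continuous and 0-based; theta = 0 points along +x (image columns) and
#' increases towards +y (image rows).
#'
#' @slot pole numeric length-2 (x, y) pole position, pixels.
#' @slot radii numeric vector of N node radii (pixels, all > 0).
#' @slot coef numeric vector of N B-spline coefficients.
#' @slot degree integer spline degree (default 2).
#'
#' @export
setClass("PolarContour",
  representation(pole = "numeric", radii = "numeric",
                 coef = "numeric", degree = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@pole) != 2 || any(!is.finite(object@pole)))
      msg <- c(msg, "pole must be a finite (x, y) pair")
    n <- length(object@radii)
    if (n < 8) msg <- c(msg, "at least 8 nodes are required")
    if (any(!is.finite(object@radii)) || any(object@radii <= 0))
      msg <- c(msg, "all node radii must be positive and finite")
    if (length(object@coef) != n)
      msg <- c(msg, "coefficient vector must match node count")
    if (object@degree < 1L) msg <- c(msg, "degree must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' DoubleContour: coupled nucleus + cytoplasm contour pair
#'
#' Two \linkS4class{PolarContour}s sharing one pole; the inner layer follows
#' the nucleus-cytoplasm interface and the outer layer the cytoplasm-background
#' interface.  At every node angle the cytoplasm radius must exceed the
#' nucleus radius by at least \code{margin} pixels.
#'
#' @slot nucleus,cytoplasm \linkS4class{PolarContour} layers (shared pole,
#'   same node count).
#' @slot margin numeric minimal radial separation (pixels).
#' @export
setClass("DoubleContour",
  representation(nucleus = "PolarContour", cytoplasm = "PolarContour",
                 margin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@nucleus@pole, object@cytoplasm@pole,
                          tolerance = 1e-9)))
      msg <- c(msg, "nucleus and cytoplasm must share the same pole")
    if (length(object@nucleus@radii) != length(object@cytoplasm@radii))
      msg <- c(msg, "both layers must have the same node count")
    if (object@margin < 0) msg <- c(msg, "margin must be >= 0")
    if (any(object@cytoplasm@radii < object@nucleus@radii + object@margin - 1e-9))
      msg <- c(msg, "cytoplasm radius must be >= nucleus radius + margin at every node")
    if (length(msg)) msg else TRUE
  })

#' CellTrack: per-frame contours and centroid trajectory of one cell
#'
#' @slot cellId integer cell identifier.
#' @slot mode "one_layer" or "double".
#' @slot contours list (length = number of frames) of \linkS4class{PolarContour}
#'   or \linkS4class{DoubleContour}.
#' @slot status character per-frame status: "tracked", "degenerate" or "lost".
#'   A degenerate/lost frame carries the last valid contour, frozen.
#' @slot centroids numeric matrix (frames x 2) of contour centroids (x, y).
#' @export
setClass("CellTrack",
  representation(cellId = "integer", mode = "character",
                 contours = "list", status = "character",
                 centroids = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("one_layer", "double"))
      msg <- c(msg, "mode must be 'one_layer' or 'double'")
    nf <- length(object@contours)
    if (length(object@status) != nf)
      msg <- c(msg, "status length must equal number of frames")
    if (nrow(object@centroids) != nf)
      msg <- c(msg, "centroid matrix must have one row per frame")
    if (!all(object@status %in% c("tracked", "degenerate", "lost")))
      msg <- c(msg, "invalid status value")
    if (length(msg)) msg else TRUE
  })

#' SceneTruth: ground truth for a synthetic scene
#'
#' Compact ground truth of a generated recording: per-cell shapes (dense polar
#' radius tables), per-frame centers, true cytoplasm waveforms and blur
#' schedule.  Per-frame binary masks are reconstructed on demand with
#' \code{\link{truthMask}}.
#'
#' @slot dim integer (height, width) of the frames.
#' @slot nFrames integer number of frames.
#' @slot shapes list per cell: list(radii = dense radius table over
#'   \code{angles}, nucleusRadii = same for the nucleus).
#' @slot angles numeric dense angle grid shared by all shape tables.
#' @slot centers list per cell of (frames x 2) center trajectories.
#' @slot waveforms numeric matrix (frames x cells): true cytoplasm intensity.
#' @slot blurFrames integer indices of out-of-focus (blurred) frames.
#' @slot transforms list of per-frame-pair global motion transforms (or empty).
#' @export
setClass("SceneTruth",
  representation(dim = "integer", nFrames = "integer", shapes = "list",
                 angles = "numeric", centers = "list", waveforms = "matrix",
                 blurFrames = "integer", transforms = "list"))

#' FrameTransform: geometric transform between consecutive frames
#'
#' Least-squares transform \eqn{T} mapping landmark positions in frame f to
#' frame f+1, one of "translation" (2 parameters), "affine" (6) or
#' "polynomial-2" (12).
#'
#' @slot model character model name.
#' @slot params numeric parameter matrix (terms x 2), columns = (x', y').
#' @slot frames integer pair (f, f+1), 1-based.
#' @slot rms numeric residual root-mean-square (pixels).
#' @export
setClass("FrameTransform",
  representation(model = "character", params = "matrix",
                 frames = "integer", rms = "numeric"),
  validity = function(object) {
    if (!object@model %in% c("translation", "affine", "polynomial-2"))
      return("model must be translation, affine or polynomial-2")
    TRUE
  })

setMethod("show", "PolarContour", function(object) {
  cat(sprintf("PolarContour: %d nodes, degree %d, pole (%.2f, %.2f), mean radius %.2f px\n",
              length(object@radii), object@degree,
              object@pole[1], object@pole[2], mean(object@radii)))
})

setMethod("show", "DoubleContour", function(object) {
  cat(sprintf("DoubleContour: %d nodes, pole (%.2f, %.2f), mean r_nuc %.2f / r_cyt %.2f px\n",
              length(object@cytoplasm@radii), object@cytoplasm@pole[1],
              object@cytoplasm@pole[2], mean(object@nucleus@radii),
              mean(object@cytoplasm@radii)))
})

setMethod("show", "CellTrack", function(object) {
  cat(sprintf("CellTrack %d (%s): %d frames (%d tracked, %d degenerate, %d lost)\n",
              object@cellId, object@mode, length(object@status),
              sum(object@status == "tracked"),
              sum(object@status == "degenerate"),
              sum(object@status == "lost")))
})

setMethod("show", "FrameTransform", function(object) {
  cat(sprintf("FrameTransform %s: frames %d -> %d, residual RMS %.3g px\n",
              object@model, object@frames[1], object@frames[2], object@rms))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d cells, %d frames, %dx%d px, %d blurred frames\n",
              length(object@shapes), object@nFrames, object@dim[1],
              object@dim[2], length(object@blurFrames)))
})
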