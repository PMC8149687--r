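## Frame-to-frame tracking loop and signal extraction.

#' Track cells through a recording
#'
#' Runs the frame loop: contours converged on frame t seed the segmentation
#' of frame t+1; the area-stability reference is the previous frame's
#' post-segmentation area.  Cells whose contour degenerates keep their last
#' valid contour, frozen and flagged, for the remaining frames (they may
#' recover).  Images are internally normalized to [0, 1] over the stack for
#' the energy computation; extracted signals (see
#' \code{\link{extractSignals}}) always use the original intensities.
#'
#' @param stack numeric 3D array (height x width x frames) or list of
#'   matrices.
#' @param init either a data.frame of initialization ellipses (columns
#'   cell_id, cx, cy, a, b, angle_deg) or a list of ready
#'   \linkS4class{PolarContour}/\linkS4class{DoubleContour} objects.
#' @param mode "one_layer" or "double".
#' @param config an \code{\link{energyConfig}}.
#' @param descent a \code{\link{descentConfig}}.
#' @param nNodes contour nodes when initializing from ellipses (default 32).
#' @param verbose print a one-line per-frame summary.
#' @return list of \linkS4class{CellTrack}, one per cell.
#' @export
trackCells <- function(stack, init, mode = c("one_layer", "double"),
                       config = energyConfig(), descent = descentConfig(),
                       nNodes = 32L, verbose = FALSE) {
  mode <- match.arg(mode)
  stack <- asStack(stack)
  nf <- dim(stack)[3]
  if (nf < 1) stop("empty stack")
  rng <- range(stack)
  den <- if (diff(rng) > 0) diff(rng) else 1
  norm <- function(t) (stack[, , t] - rng[1]) / den

  if (is.data.frame(init)) {
    cells <- initializeContours(norm(1), init, mode, config, descent, nNodes)
    cfgs <- attr(cells, "configs")
  } else {
    cells <- segmentFrame(norm(1), init, config = config, descent = descent)$cells
    # derive missing per-cell area bounds from the frame-1 contour areas
    cfgs <- lapply(cells, function(cell) {
      ci <- config
      a1 <- contourArea(outerLayer(cell))
      if (!is.finite(ci$areaMin)) ci$areaMin <- 0.55 * a1
      if (!is.finite(ci$areaMax)) ci$areaMax <- 1.3 * a1
      if (ci$rhoGuard <= 0) ci$rhoGuard <- 0.5 * sqrt(a1 / pi)
      ci
    })
  }
  nc <- length(cells)
  contours <- replicate(nc, vector("list", nf), simplify = FALSE)
  status <- matrix("tracked", nf, nc)
  cents <- replicate(nc, matrix(NA_real_, nf, 2), simplify = FALSE)
  areas <- rep(NA_real_, nc)
  record <- function(t, st) {
    for (i in seq_len(nc)) {
      contours[[i]][[t]] <<- cells[[i]]
      status[t, i] <<- st[i]
      cents[[i]][t, ] <<- polygonCentroid(contourPolygon(outerLayer(cells[[i]])))
      areas[i] <<- contourArea(outerLayer(cells[[i]]))
    }
  }
  record(1, rep("tracked", nc))
  for (t in seq_len(nf)[-1]) {
    sf <- segmentFrame(norm(t), cells, prevAreas = areas,
                       config = cfgs, descent = descent)
    cells <- sf$cells
    record(t, sf$status)
    if (verbose)
      message(sprintf("frame %d: %s (iters %s)", t,
                      paste(sf$status, collapse = ","),
                      paste(sf$iterations, collapse = ",")))
  }
  lapply(seq_len(nc), function(i)
    new("CellTrack", cellId = i, mode = mode, contours = contours[[i]],
        status = status[, i], centroids = cents[[i]]))
}

# coerce list-of-matrices or array to H x W x T array
asStack <- function(stack) {
  if (is.list(stack)) {
    stack <- array(unlist(stack), dim = c(dim(stack[[1]]), length(stack)))
  }
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  stack
}

#' @rdname trackAccessors
#' @export
trackCentroids <- function(track) track@centroids

#' CellTrack accessors
#'
#' \code{trackCentroids}, \code{trackStatus} and \code{trackContour} read the
#' centroid trajectory, the per-frame status vector and the contour at one
#' frame.
#'
#' @param track a \linkS4class{CellTrack}.
#' @param frame frame index (1-based).
#' @name trackAccessors
#' @rdname trackAccessors
#' @export
trackStatus <- function(track) track@status

#' @rdname trackAccessors
#' @export
trackContour <- function(track, frame) track@contours[[frame]]

#' Extract per-cell intensity traces
#'
#' Mean intensity over the tracked region on every frame: the contour
#' interior in one-layer mode, the cytoplasm ring (cytoplasm interior minus
#' nucleus interior) in double mode, so nucleus pixels never dilute the
#' signal.  Frames with degenerate/lost status use the frozen contour and are
#' flagged in the \code{status} column.
#'
#' @param stack numeric 3D array or list of matrices (original intensities).
#' @param tracks list of \linkS4class{CellTrack} from \code{\link{trackCells}}.
#' @return data.frame with columns frame, cell_id, mean_intensity, n_pixels,
#'   status.
#' @export
extractSignals <- function(stack, tracks) {
  stack <- asStack(stack)
  nf <- dim(stack)[3]
  dm <- dim(stack)[1:2]
  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    stopifnot(length(tr@status) == nf)
    mi <- numeric(nf); np <- integer(nf)
    for (t in seq_len(nf)) {
      cell <- tr@contours[[t]]
      m <- if (is(cell, "DoubleContour")) {
        contourMask(cell@cytoplasm, dm) & !contourMask(cell@nucleus, dm)
      } else contourMask(cell, dm)
      np[t] <- sum(m)
      mi[t] <- if (np[t] > 0) mean(stack[, , t][m]) else NA_real_
    }
    out[[i]] <- data.frame(frame = seq_len(nf), cell_id = tr@cellId,
                           mean_intensity = mi, n_pixels = np,
                           status = tr@status)
  }
  do.call(rbind, out)
}
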