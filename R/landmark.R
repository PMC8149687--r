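## Landmark-based geometric transforms and ROI propagation: a per-frame
## transform T is fit by least squares to tracked cell centroids,
## theta* = argmin sum_i ||x_i^{f+1} - T(x_i^f)||^2, and applied to manually
## drawn ROIs so they follow the tissue motion.

transformDesign <- function(pts, model) {
  x <- pts[, 1]; y <- pts[, 2]
  switch(model,
         translation = cbind(rep(1, length(x))),
         affine = cbind(x, y, 1),
         `polynomial-2` = cbind(1, x, y, x^2, x * y, y^2),
         stop("unknown transform model"))
}

minLandmarks <- c(translation = 1, affine = 3, `polynomial-2` = 6)

#' Estimate the frame-to-frame geometric transform
#'
#' Linear least-squares fit of a geometric transform T mapping landmark
#' positions (tracked cell centroids) in frame f to frame f+1.  Models:
#' "translation" (2 parameters), "affine" (6), "polynomial-2" (degree-2
#' polynomial in x and y, 12).  A rank-deficient or under-determined system
#' falls back to the next simpler model with a warning.
#'
#' @param landmarksF,landmarksF1 numeric matrices (n x 2) of corresponding
#'   points in frames f and f+1.
#' @param model "translation", "affine" or "polynomial-2".
#' @param frames integer pair recorded in the result (default c(1, 2)).
#' @return a \linkS4class{FrameTransform}.
#' @export
estimateFrameTransform <- function(landmarksF, landmarksF1, model = "affine",
                                   frames = c(1L, 2L)) {
  landmarksF <- as.matrix(landmarksF); landmarksF1 <- as.matrix(landmarksF1)
  stopifnot(nrow(landmarksF) == nrow(landmarksF1), ncol(landmarksF) == 2)
  n <- nrow(landmarksF)
  order <- c("polynomial-2", "affine", "translation")
  model <- match.arg(model, order)
  for (m in order[seq(match(model, order), 3)]) {
    if (n < minLandmarks[[m]]) next
    if (m == "translation") {
      d <- colMeans(landmarksF1 - landmarksF)
      pred <- sweep(landmarksF, 2, d, "+")
      params <- matrix(d, 1, 2, dimnames = list(NULL, c("x", "y")))
    } else {
      X <- transformDesign(landmarksF, m)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) next
      params <- qr.coef(qrX, landmarksF1)
      pred <- X %*% params
      colnames(params) <- c("x", "y")
    }
    if (m != model)
      warning("landmark system under-determined for '", model,
              "'; fell back to '", m, "'")
    rms <- sqrt(mean(rowSums((landmarksF1 - pred)^2)))
    return(new("FrameTransform", model = m, params = params,
               frames = as.integer(frames), rms = rms))
  }
  stop("not enough landmarks for any transform model")
}

#' Apply a frame transform to points
#'
#' @param transform a \linkS4class{FrameTransform}.
#' @param pts numeric matrix (n x 2).
#' @return transformed points (n x 2).
#' @export
applyTransform <- function(transform, pts) {
  pts <- as.matrix(pts)
  if (transform@model == "translation")
    return(sweep(pts, 2, transform@params[1, ], "+"))
  unname(transformDesign(pts, transform@model) %*% transform@params)
}

#' Invert a frame transform
#'
#' Analytic inverse for translation and affine transforms; degree-2
#' polynomial transforms have no closed-form inverse and signal an error of
#' class \code{"beas_noninvertible"} (backward ROI propagation is refused).
#'
#' @param transform a \linkS4class{FrameTransform}.
#' @return the inverse \linkS4class{FrameTransform}.
#' @export
invertTransform <- function(transform) {
  fr <- rev(transform@frames)
  if (transform@model == "translation")
    return(new("FrameTransform", model = "translation",
               params = -transform@params, frames = as.integer(fr),
               rms = transform@rms))
  if (transform@model == "affine") {
    A <- t(transform@params[1:2, ])            # 2x2 linear part
    b <- transform@params[3, ]
    Ai <- tryCatch(solve(A), error = function(e)
      stop(errorCondition("singular affine transform",
                          class = c("beas_noninvertible", "error"))))
    params <- rbind(t(Ai), as.numeric(-Ai %*% b))
    colnames(params) <- c("x", "y")
    return(new("FrameTransform", model = "affine", params = params,
               frames = as.integer(fr), rms = transform@rms))
  }
  stop(errorCondition("polynomial-2 transforms cannot be inverted analytically",
                      class = c("beas_noninvertible", "error")))
}

#' Estimate transforms along a whole recording
#'
#' Fits one transform per consecutive frame pair from tracked cell
#' centroids; cells not in "tracked" status on both frames of a pair are
#' excluded from that fit.
#'
#' @param tracks list of \linkS4class{CellTrack}.
#' @param model transform model (default "affine").
#' @return list of \linkS4class{FrameTransform}, length frames - 1.
#' @export
trackTransforms <- function(tracks, model = "affine") {
  nf <- length(tracks[[1]]@status)
  lapply(seq_len(nf - 1), function(f) {
    use <- vapply(tracks, function(tr)
      tr@status[f] == "tracked" && tr@status[f + 1] == "tracked", logical(1))
    a <- do.call(rbind, lapply(tracks[use], function(tr) tr@centroids[f, ]))
    b <- do.call(rbind, lapply(tracks[use], function(tr) tr@centroids[f + 1, ]))
    estimateFrameTransform(a, b, model, frames = c(f, f + 1))
  })
}

#' Propagate ROIs through a recording
#'
#' Applies the chained per-frame transforms to the ROI vertices, forward from
#' the frame where each ROI was drawn and backward via the analytic inverse
#' (refused with a flag for polynomial-2 transforms).
#'
#' @param rois list of ROIs: each list(roi_id, vertices = n x 2 matrix,
#'   frame = frame drawn on (default 1)).
#' @param transforms list of \linkS4class{FrameTransform} covering frame
#'   pairs (1,2) .. (T-1,T).
#' @return list of tracked ROIs: each list(roi_id, vertices = list per frame,
#'   backwardRefused flag).
#' @export
propagateROIs <- function(rois, transforms) {
  nf <- length(transforms) + 1
  lapply(rois, function(roi) {
    f0 <- if (is.null(roi$frame)) 1L else as.integer(roi$frame)
    verts <- vector("list", nf)
    verts[[f0]] <- as.matrix(roi$vertices)
    if (f0 < nf) for (f in f0:(nf - 1))
      verts[[f + 1]] <- applyTransform(transforms[[f]], verts[[f]])
    backwardRefused <- FALSE
    if (f0 > 1) {
      for (f in seq(f0 - 1, 1)) {
        inv <- tryCatch(invertTransform(transforms[[f]]),
                        beas_noninvertible = function(e) NULL)
        if (is.null(inv)) { backwardRefused <- TRUE; break }
        verts[[f]] <- applyTransform(inv, verts[[f + 1]])
      }
    }
    list(roi_id = roi$roi_id, vertices = verts,
         backwardRefused = backwardRefused)
  })
}

#' Extract signals from tracked ROIs
#'
#' Per-frame mean intensity over each ROI's rasterized interior; an ROI fully
#' outside the image yields NA with status "lost".
#'
#' @param stack numeric array (height x width x frames).
#' @param trackedROIs result of \code{\link{propagateROIs}}.
#' @return data.frame with columns frame, roi_id, mean_intensity, n_pixels,
#'   status.
#' @export
extractROISignals <- function(stack, trackedROIs) {
  stack <- asStack(stack)
  nf <- dim(stack)[3]
  h <- dim(stack)[1]; w <- dim(stack)[2]
  out <- list()
  for (roi in trackedROIs) {
    mi <- rep(NA_real_, nf); np <- integer(nf); st <- rep("tracked", nf)
    for (t in seq_len(nf)) {
      v <- roi$vertices[[t]]
      if (is.null(v)) { st[t] <- "lost"; next }
      x0 <- max(0, floor(min(v[, 1]))); x1 <- min(w - 1, ceiling(max(v[, 1])))
      y0 <- max(0, floor(min(v[, 2]))); y1 <- min(h - 1, ceiling(max(v[, 2])))
      if (x1 < x0 || y1 < y0) { st[t] <- "lost"; next }
      xs <- x0:x1; ys <- y0:y1
      pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
      ins <- pointsInPolygon(pts, v)
      np[t] <- sum(ins)
      if (np[t] == 0) { st[t] <- "lost"; next }
      mi[t] <- mean(stack[, , t][cbind(pts[ins, 2] + 1, pts[ins, 1] + 1)])
    }
    out[[length(out) + 1]] <-
      data.frame(frame = seq_len(nf), roi_id = roi$roi_id,
                 mean_intensity = mi, n_pixels = np, status = st)
  }
  do.call(rbind, out)
}
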