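## Contour geometry: constructors, evaluation, polygons, area, centroid,
## pole re-centering with node resampling, and local mean curvature.

#' Construct a PolarContour from node radii
#'
#' @param pole numeric (x, y) pole position.
#' @param radii numeric vector of N >= 8 positive node radii at the regular
#'   angles \eqn{\theta_i = (i-1)\,2\pi/N}.
#' @param degree spline degree (default 2).
#' @return a \linkS4class{PolarContour} whose spline interpolates the radii.
#' @export
polarContour <- function(pole, radii, degree = 2L) {
  new("PolarContour", pole = as.numeric(pole), radii = as.numeric(radii),
      coef = fitCoefficients(radii, degree), degree = as.integer(degree))
}

#' @rdname accessors
#' @param contour a \linkS4class{PolarContour}.
#' @export
contourPole <- function(contour) contour@pole

#' Accessors for PolarContour
#'
#' \code{contourPole}, \code{nodeRadii}, \code{nodeAngles}, \code{splineCoefs}
#' and \code{nNodes} read the pole, node radii, regular node angles, B-spline
#' coefficients and node count.
#'
#' @name accessors
#' @rdname accessors
#' @export
nodeRadii <- function(contour) contour@radii

#' @rdname accessors
#' @export
nodeAngles <- function(contour) {
  n <- length(contour@radii)
  seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
}

#' @rdname accessors
#' @export
splineCoefs <- function(contour) contour@coef

#' @rdname accessors
#' @export
nNodes <- function(contour) length(contour@radii)

#' Initialize a contour from an ellipse
#'
#' Builds the interpolating polar contour of the ellipse with the given
#' center, semi-axes and orientation; this is the user-facing initialization
#' (an ellipse roughly overlapping the target cell body).
#'
#' @param center numeric (x, y), pixels.
#' @param semiAxes numeric (a, b), both > 0, pixels.
#' @param orientation rotation of the major axis, radians (default 0).
#' @param nNodes number of contour nodes (default 32).
#' @param degree spline degree (default 2).
#' @return a \linkS4class{PolarContour}.
#' @examples
#' ell <- makeEllipseContour(c(0, 0), c(12, 8), 0, 32)
#' range(nodeRadii(ell))  # 8 .. 12
#' @export
makeEllipseContour <- function(center, semiAxes, orientation = 0,
                               nNodes = 32L, degree = 2L) {
  if (length(semiAxes) != 2 || any(semiAxes <= 0))
    stop("semiAxes must be two positive lengths")
  if (nNodes < 8) stop("at least 8 nodes are required")
  a <- semiAxes[1]; b <- semiAxes[2]
  th <- seq(0, 2 * pi, length.out = nNodes + 1)[seq_len(nNodes)]
  phi <- th - orientation
  r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  polarContour(center, r, degree)
}

#' Evaluate the contour radius at arbitrary angles
#'
#' \eqn{r(\theta) = \sum_k c[k]\,\beta^d(\theta/h - k)} with periodic
#' wrap-around of the coefficient index; angles are taken modulo 2\eqn{\pi}.
#'
#' @param contour a \linkS4class{PolarContour}.
#' @param angles numeric vector of angles (radians).
#' @return numeric vector of radii.
#' @export
evaluateRadius <- function(contour, angles) {
  splineEval(contour@coef, contour@degree, angles)$r
}

# radius plus first/second angular derivatives at given angles
radiusDerivatives <- function(contour, angles) {
  if (contour@degree >= 2L) {
    ev <- splineEval(contour@coef, contour@degree, angles, derivatives = 2L)
    return(ev)
  }
  # degree 1: circular finite differences on the node grid
  r <- contour@radii
  n <- length(r)
  h <- 2 * pi / n
  ev <- splineEval(contour@coef, contour@degree, angles, derivatives = 0L)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  d1n <- (r[ip] - r[im]) / (2 * h)
  d2n <- (r[ip] - 2 * r + r[im]) / h^2
  idx <- round(angles / h) %% n + 1
  ev$d1 <- d1n[idx]
  ev$d2 <- d2n[idx]
  ev
}

#' Dense closed polygon of a contour
#'
#' Samples the boundary at \code{nNodes * samplesPerSegment} angles and maps to
#' image coordinates \eqn{pole + r(\theta)(\cos\theta, \sin\theta)}.  Vertices
#' are ordered by increasing theta (counter-clockwise in the x-right, y-down
#' pixel frame) and the polygon is implicitly closed (last vertex connects to
#' the first).
#'
#' @param contour a \linkS4class{PolarContour}.
#' @param samplesPerSegment samples per node interval (default 8).
#' @return numeric matrix with columns x, y.
#' @export
contourPolygon <- function(contour, samplesPerSegment = 8L) {
  n <- length(contour@radii) * samplesPerSegment
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  r <- evaluateRadius(contour, th)
  cbind(x = contour@pole[1] + r * cos(th),
        y = contour@pole[2] + r * sin(th))
}

# shoelace area of a closed polygon (matrix with columns x, y); absolute value
shoelaceArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygonCentroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Enclosed area of a contour
#'
#' Shoelace area of the densely sampled boundary polygon.
#'
#' @inheritParams contourPolygon
#' @return positive area in px^2.
#' @export
contourArea <- function(contour, samplesPerSegment = 8L) {
  shoelaceArea(contourPolygon(contour, samplesPerSegment))
}

#' Re-center the pole and resample the nodes
#'
#' Moves the pole to the area centroid of the contour polygon, converts the
#' existing node points to the new polar frame, and linearly interpolates
#' (r', theta') back onto the regular angle grid; coefficients are refitted.
#' This keeps the pole inside the cell as it moves between frames.
#'
#' @param contour a \linkS4class{PolarContour}.
#' @return a new \linkS4class{PolarContour}, or signals an error of class
#'   \code{"beas_degenerate"} when the centroid falls outside the contour or a
#'   resampled radius is not positive (the caller marks the cell lost).
#' @export
recentreAndResample <- function(contour) {
  poly <- contourPolygon(contour)
  cen <- polygonCentroid(poly)
  if (!pointsInPolygon(rbind(cen), poly))
    stop(errorCondition("pole centroid outside contour",
                        class = c("beas_degenerate", "error")))
  resampleToPole(contour, cen)
}

# resample a contour's dense boundary onto the regular angle grid about an
# arbitrary new pole (linear interpolation in (theta', r'))
resampleToPole <- function(contour, pole) {
  poly <- contourPolygon(contour)
  dx <- poly[, 1] - pole[1]; dy <- poly[, 2] - pole[2]
  th <- atan2(dy, dx) %% (2 * pi)
  rr <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; rr <- rr[o]
  # periodic linear interpolation: extend one point on each side
  thx <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rrx <- c(rr[length(rr)], rr, rr[1])
  n <- length(contour@radii)
  grid <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  newr <- approx(thx, rrx, xout = grid, ties = "ordered")$y
  if (any(!is.finite(newr)) || any(newr <= 0))
    stop(errorCondition("resampled radius not positive",
                        class = c("beas_degenerate", "error")))
  polarContour(pole, newr, contour@degree)
}

#' Local mean curvature at the contour nodes
#'
#' Curvature of the planar curve \eqn{(r(\theta), \theta)} evaluated at each
#' node from the analytic B-spline derivatives,
#' \eqn{\kappa = (r^2 + 2 r'^2 - r r'') / (r^2 + r'^2)^{3/2}}; positive for
#' convex boundaries (a circle of radius R has \eqn{\kappa = 1/R} everywhere).
#'
#' @param contour a \linkS4class{PolarContour}.
#' @return numeric vector of N curvatures (1/px).
#' @export
localMeanCurvature <- function(contour) {
  ev <- radiusDerivatives(contour, nodeAngles(contour))
  r <- ev$r; d1 <- ev$d1; d2 <- ev$d2
  (r^2 + 2 * d1^2 - r * d2) / (r^2 + d1^2)^1.5
}

#' Binary mask of a contour interior
#'
#' Rasterizes the star-shaped interior over a full image grid: pixel (x, y)
#' is inside iff its distance to the pole is at most \eqn{r(\theta)} at its
#' polar angle.  Pixel centers sit at integer 0-based coordinates.
#'
#' @param contour a \linkS4class{PolarContour}.
#' @param dim integer (height, width) of the target image.
#' @return logical matrix (height x width).
#' @export
contourMask <- function(contour, dim) {
  h <- dim[1]; w <- dim[2]
  m <- matrix(FALSE, h, w)
  rmax <- max(contour@radii) * 1.6 + 2
  x0 <- max(0, floor(contour@pole[1] - rmax)); x1 <- min(w - 1, ceiling(contour@pole[1] + rmax))
  y0 <- max(0, floor(contour@pole[2] - rmax)); y1 <- min(h - 1, ceiling(contour@pole[2] + rmax))
  if (x1 < x0 || y1 < y0) return(m)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - contour@pole[1]
  gy <- matrix(ys, length(ys), length(xs)) - contour@pole[2]
  th <- atan2(gy, gx) %% (2 * pi)
  rr <- sqrt(gx^2 + gy^2)
  nT <- 512L
  tab <- evaluateRadius(contour, seq(0, 2 * pi, length.out = nT + 1)[seq_len(nT)])
  rb <- tab[(round(th * (nT / (2 * pi))) %% nT) + 1]
  m[ys + 1, xs + 1] <- matrix(rr <= rb, length(ys), length(xs))
  m
}

# signed "inside" test for star-shaped contours at continuous points (n x 2);
# the boundary radius is read from a 512-entry dense table (one spline
# evaluation per call instead of one per point)
insideContour <- function(contour, pts) {
  dx <- pts[, 1] - contour@pole[1]; dy <- pts[, 2] - contour@pole[2]
  th <- atan2(dy, dx) %% (2 * pi)
  if (length(dx) < 200) {
    rb <- evaluateRadius(contour, th)
  } else {
    nT <- 512L
    tab <- evaluateRadius(contour,
                          seq(0, 2 * pi, length.out = nT + 1)[seq_len(nT)])
    rb <- tab[(round(th * (nT / (2 * pi))) %% nT) + 1]
  }
  sqrt(dx^2 + dy^2) <= rb
}

# general even-odd point-in-polygon (mgcv); poly is a matrix with columns x, y
pointsInPolygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, as.matrix(pts)))
}

#' Intersection over union of two binary masks
#'
#' @param maskA,maskB logical matrices of identical shape.
#' @return scalar in [0, 1]; two empty masks give 0 (with attribute
#'   \code{empty = TRUE}).
#' @export
iouScore <- function(maskA, maskB) {
  stopifnot(identical(dim(maskA), dim(maskB)))
  un <- sum(maskA | maskB)
  if (un == 0) return(structure(0, empty = TRUE))
  sum(maskA & maskB) / un
}
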