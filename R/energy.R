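## Data-attachment (localized Yezzi) and regularization/competition energies
## with their per-node radial gradients.  Forces are scalar per node, positive
## = outward (radius increase).

# node positions and outward unit normals
contourGeometry <- function(contour) {
  th <- nodeAngles(contour)
  ev <- radiusDerivatives(contour, th)
  r <- ev$r; d1 <- ev$d1
  px <- contour@pole[1] + r * cos(th)
  py <- contour@pole[2] + r * sin(th)
  # tangent T = r'(cos,sin) + r(-sin,cos); outward normal = (T_y, -T_x)/|T|
  tx <- d1 * cos(th) - r * sin(th)
  ty <- d1 * sin(th) + r * cos(th)
  nt <- sqrt(tx^2 + ty^2)
  list(theta = th, r = r, px = px, py = py,
       nx = ty / nt, ny = -tx / nt)
}

# bilinear interpolation of image at continuous 0-based (x, y); border-replicated
bilinearAt <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  (1 - fy) * ((1 - fx) * image[i00] + fx * image[i01]) +
    fy * ((1 - fx) * image[i10] + fx * image[i11])
}

# Band statistics for all nodes at once: inside/outside means along the node
# normals (rho samples each side at unit spacing, inward samples truncated at
# the node radius, samples off the image dropped).  Intensities are bilinear
# lookups at the continuous sample positions, so the energy varies smoothly
# with sub-pixel node displacements; for noise robustness the band is three
# pixels wide (the normal column plus one column on each tangential side).
bandStats <- function(image, contour, rho, geom = contourGeometry(contour),
                      rGuard = 0, outCap = NULL) {
  h <- nrow(image); w <- ncol(image)
  n <- length(geom$r)
  off <- seq_len(rho) - 0.5
  tang <- c(-1, 0, 1)                                    # tangential columns
  ox <- outer(geom$nx, off); oy <- outer(geom$ny, off)   # n x rho
  # tangent unit vector = outward normal rotated +90 deg
  tx <- -geom$ny; ty <- geom$nx
  cb <- function(f) do.call(cbind, lapply(tang, f))
  xin <- cb(function(s) geom$px - ox + s * tx)
  yin <- cb(function(s) geom$py - oy + s * ty)
  xout <- cb(function(s) geom$px + ox + s * tx)
  yout <- cb(function(s) geom$py + oy + s * ty)
  # inward samples stay in the outer half of the radius and outside the
  # per-cell pole-exclusion radius rGuard: keeps the inside statistics
  # cytoplasmic (clear of a dark nucleus) even when a node is pulled inward
  inRange <- outer(pmin(geom$r * 0.5, geom$r - rGuard), off, ">")
  inRange <- do.call(cbind, rep(list(inRange), length(tang)))
  okIn <- xin >= 0 & xin <= w - 1 & yin >= 0 & yin <= h - 1 & inRange
  okOut <- xout >= 0 & xout <= w - 1 & yout >= 0 & yout <= h - 1
  if (!is.null(outCap)) {                                # e.g. stay inside the
    oc <- outer(pmax(outCap, 1.5), off, ">")             # cytoplasm ring
    okOut <- okOut & do.call(cbind, rep(list(oc), length(tang)))
  }
  m <- n * rho * length(tang)
  vin <- numeric(m); vout <- numeric(m)
  if (any(okIn)) vin[okIn] <- bilinearAt(image, xin[okIn], yin[okIn])
  if (any(okOut)) vout[okOut] <- bilinearAt(image, xout[okOut], yout[okOut])
  dim(vin) <- dim(vout) <- dim(okIn)
  nIn <- rowSums(okIn); nOut <- rowSums(okOut)
  uIn <- rowSums(vin) / nIn; uIn[nIn == 0] <- NA_real_
  uOut <- rowSums(vout) / nOut; uOut[nOut == 0] <- NA_real_
  iNode <- bilinearAt(image, geom$px, geom$py)
  list(uIn = uIn, uOut = uOut, nIn = nIn, nOut = nOut, iNode = iNode)
}

#' Normal band pixels of one contour node
#'
#' The mask in which local statistics are estimated for a node: a column of
#' pixels along the node's normal, \code{rho} samples at unit spacing on the
#' inward and on the outward side.  Sample positions are rounded to pixels,
#' clipped to the image, and inward samples never reach past the pole.
#'
#' @param dim integer (height, width) of the image.
#' @param contour a \linkS4class{PolarContour}.
#' @param nodeIndex node index (1-based).
#' @param rho neighborhood radius (samples per side).
#' @return list with integer matrices \code{inside} and \code{outside}
#'   (columns x, y; 0-based, duplicates removed); either may have zero rows.
#' @export
localBand <- function(dim, contour, nodeIndex, rho) {
  g <- contourGeometry(contour)
  k <- nodeIndex
  off <- seq_len(rho) - 0.5
  mk <- function(sgn, clampPole) {
    x <- round(g$px[k] + sgn * g$nx[k] * off)
    y <- round(g$py[k] + sgn * g$ny[k] * off)
    ok <- x >= 0 & x < dim[2] & y >= 0 & y < dim[1]
    if (clampPole) ok <- ok & off < g$r[k]
    p <- unique(cbind(x = x[ok], y = y[ok]))
    p
  }
  list(inside = mk(-1, TRUE), outside = mk(1, FALSE))
}

#' Localized inside/outside means at one node
#'
#' Arithmetic means of the image over the inside and outside band pixel sets
#' of \code{\link{localBand}}.
#'
#' @param image numeric matrix (height x width).
#' @inheritParams localBand
#' @return list \code{uIn}, \code{uOut} (NA when the band is empty) and
#'   \code{defined} (TRUE when both means exist).
#' @export
localizedMeans <- function(image, contour, nodeIndex, rho) {
  b <- localBand(dim(image), contour, nodeIndex, rho)
  m <- function(p) if (nrow(p) > 0)
    mean(image[cbind(p[, 2] + 1, p[, 1] + 1)]) else NA_real_
  uIn <- m(b$inside); uOut <- m(b$outside)
  list(uIn = uIn, uOut = uOut, defined = is.finite(uIn) && is.finite(uOut))
}

#' Localized Yezzi radial force at one node
#'
#' First variation of the localized Yezzi criterion
#' \eqn{F = -(u_{in} - u_{out})^2}: the signed radial force
#' \eqn{(u_{in}-u_{out})\left(\frac{I(x)-u_{in}}{n_{in}} +
#' \frac{I(x)-u_{out}}{n_{out}}\right)} (positive = outward) moves the node
#' toward the configuration of maximal mean separation.  Zero when either
#' band is empty.
#'
#' @inheritParams localizedMeans
#' @return scalar radial force.
#' @export
yezziForce <- function(image, contour, nodeIndex, rho) {
  b <- localBand(dim(image), contour, nodeIndex, rho)
  if (nrow(b$inside) == 0 || nrow(b$outside) == 0) return(0)
  uIn <- mean(image[cbind(b$inside[, 2] + 1, b$inside[, 1] + 1)])
  uOut <- mean(image[cbind(b$outside[, 2] + 1, b$outside[, 1] + 1)])
  g <- contourGeometry(contour)
  iN <- bilinearAt(image, g$px[nodeIndex], g$py[nodeIndex])
  (uIn - uOut) * ((iN - uIn) / nrow(b$inside) + (iN - uOut) / nrow(b$outside))
}

# vectorized data force + energy for all nodes (internal fast path)
dataTerm <- function(image, contour, rho, geom = contourGeometry(contour),
                     rGuard = 0, outCap = NULL, darkInside = FALSE) {
  s <- bandStats(image, contour, rho, geom, rGuard, outCap)
  ok <- s$nIn > 0 & s$nOut > 0
  du <- s$uIn - s$uOut; du[!ok] <- 0
  # nucleus layer: the nuclear interface has a known polarity (dark inside,
  # bright outside), so bright-inside configurations earn no reward
  if (darkInside) du <- pmin(du, 0)
  force <- du * ((s$iNode - s$uIn) / pmax(s$nIn, 1) +
                 (s$iNode - s$uOut) / pmax(s$nOut, 1))
  force[!ok] <- 0
  list(force = force, energy = -sum(du^2), stats = s)
}

# dense-sampling design matrix B[s, k] = beta^d(t_s - k) on a regular grid of
# `sps` samples per node interval; cached per (n, degree, sps)
curvatureBasisMatrix <- function(n, degree, sps = 4L) {
  key <- paste0("cb_", n, "_", degree, "_", sps)
  B <- get0(key, envir = .beas_cache)
  if (!is.null(B)) return(B)
  t <- seq(0, n, length.out = n * sps + 1)[seq_len(n * sps)]
  d <- outer(t, 0:(n - 1), "-")
  d <- ((d + n / 2) %% n) - n / 2
  B <- bsplineBasis(d, degree)
  assign(key, B, envir = .beas_cache)
  B
}

#' Curvature gradient term
#'
#' Gradient of the curvature energy that penalizes concavities: the integral
#' \eqn{\int_\Gamma \kappa(x^*) H(-\kappa(x^*))\,\beta^d(x^*/h - k)\,dx^*}
#' discretized on a dense angular grid (concave arcs between nodes are seen,
#' not only the nodes themselves) and projected onto each node's basis
#' support.  Zero wherever the boundary is locally convex — a circle
#' contributes nothing.
#'
#' @param contour a \linkS4class{PolarContour}.
#' @param samplesPerSegment dense curvature samples per node interval
#'   (default 4).
#' @return list \code{gradient} (length N, \eqn{\le 0} entries at nodes whose
#'   support carries negative curvature), \code{energy}
#'   (\eqn{\int \frac{1}{2}\kappa^2 H(-\kappa)}) and \code{curvature} (dense
#'   samples).
#' @export
curvatureGradient <- function(contour, samplesPerSegment = 4L) {
  n <- length(contour@radii)
  s <- n * samplesPerSegment
  th <- seq(0, 2 * pi, length.out = s + 1)[seq_len(s)]
  ev <- radiusDerivatives(contour, th)
  k <- (ev$r^2 + 2 * ev$d1^2 - ev$r * ev$d2) / (ev$r^2 + ev$d1^2)^1.5
  neg <- pmin(k, 0)
  dth <- 2 * pi / s
  B <- curvatureBasisMatrix(n, contour@degree, samplesPerSegment)
  list(gradient = as.numeric(crossprod(B, neg)) * dth,
       energy = sum(0.5 * neg^2) * dth,
       curvature = k)
}

#' Area-range gradient
#'
#' Exact evaluation of
#' \eqn{(A - A_{min})H(A_{min} - A) + (A_{max} - A)H(A - A_{max})}:
#' negative when the area leaves the allowed range, zero inside it.  The
#' descent applies it as a uniform radial force (expand below \code{areaMin},
#' shrink above \code{areaMax}).
#'
#' @param A current contour area, px^2.
#' @param areaMin,areaMax allowed range.
#' @return scalar gradient value.
#' @export
areaGradient <- function(A, areaMin, areaMax) {
  (A - areaMin) * (areaMin > A) + (areaMax - A) * (A > areaMax)
}

#' Area-stability energy
#'
#' Relative area change against the previous frame,
#' \eqn{E_{AS} = |A_t - A_{t-1}| / A_{t-1}}; inactive (0) on the first frame.
#'
#' @param At current area; \code{APrev} previous-frame area (or NULL).
#' @param APrev previous-frame area.
#' @return scalar energy.
#' @export
areaStability <- function(At, APrev) {
  if (is.null(APrev) || !is.finite(APrev)) return(0)
  abs(At - APrev) / APrev
}

#' Proximity penalty between two contours
#'
#' For each node of contour \code{ci}, the signed Euclidean distance
#' \eqn{\psi} to the dense boundary polygon of \code{cj} (negative inside
#' \code{cj}) and the penalty \eqn{(d_T - \psi)H(d_T - \psi)}.  The returned
#' radial component is the projection of the away-from-\code{cj} direction
#' (the gradient of \eqn{\psi}) on the node's outward radial direction; the
#' descent force pushes penalized nodes away from the neighbor.
#'
#' @param ci,cj \linkS4class{PolarContour}s.
#' @param dThresh minimal distance d_T, px.
#' @param samplesPerSegment boundary samples per node interval of the
#'   neighbor polygon (default 4).
#' @return list \code{penalty}, \code{psi}, \code{radial} (each length N)
#'   and \code{energy} (sum of penalties).  \code{psi} is exact for nodes
#'   within the penalty range; for nodes that cannot be within
#'   \code{dThresh} of the neighbor a cheap lower bound is reported (their
#'   penalty is 0 either way).
#' @export
proximityPenalty <- function(ci, cj, dThresh, samplesPerSegment = 4L) {
  gi <- contourGeometry(ci)
  n <- length(gi$px)
  # nodes that cannot be within dThresh of the neighbor need no distances:
  # a cheap per-node lower bound on the distance to cj's boundary
  dc <- sqrt((gi$px - cj@pole[1])^2 + (gi$py - cj@pole[2])^2)
  rmax <- max(cj@radii) * 1.1
  cand <- dc <= rmax + dThresh + 2
  psi <- dc - rmax                   # lower bound, > dThresh for non-cand
  radial <- numeric(n)
  if (any(cand)) {
    pj <- contourPolygon(cj, samplesPerSegment)
    d2 <- outer(gi$px[cand], pj[, 1], "-")^2 +
      outer(gi$py[cand], pj[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(d2[cbind(seq_along(nearest), nearest)])
    inside <- insideContour(cj, cbind(gi$px[cand], gi$py[cand]))
    psi[cand] <- ifelse(inside, -dist, dist)
    # grad(psi) = sign(psi) * (node - nearest)/|node - nearest|
    vx <- gi$px[cand] - pj[nearest, 1]; vy <- gi$py[cand] - pj[nearest, 2]
    nv <- pmax(sqrt(vx^2 + vy^2), 1e-9)
    sg <- ifelse(inside, -1, 1)
    # radial unit = (cos th, sin th); positive -> moving outward increases psi
    radial[cand] <- sg * (vx * cos(gi$theta[cand]) +
                            vy * sin(gi$theta[cand])) / nv
  }
  pen <- pmax(dThresh - psi, 0)
  list(penalty = pen, psi = psi, radial = radial, energy = sum(pen))
}

#' Overlap penalty between two contours
#'
#' Cell-competition term: zero when the two interiors are disjoint, otherwise
#' \eqn{w_c A_c} with \eqn{A_c} the rasterized intersection area.  Inward
#' forces of magnitude \eqn{w_c} times the local penetration depth act on the
#' nodes of each contour that lie inside the other.
#'
#' @param ci,cj \linkS4class{PolarContour}s.
#' @param wComp competition weight \eqn{w_c}.
#' @return list \code{energy}, \code{area} (\eqn{A_c}), \code{forceI},
#'   \code{forceJ} (per-node radial forces, <= 0).
#' @export
overlapPenalty <- function(ci, cj, wComp) {
  ni <- length(ci@radii); nj <- length(cj@radii)
  zero <- list(energy = 0, area = 0, forceI = numeric(ni), forceJ = numeric(nj))
  # cheap bounding-circle rejection
  if (sqrt(sum((ci@pole - cj@pole)^2)) >
      max(ci@radii) * 1.2 + max(cj@radii) * 1.2 + 1) return(zero)
  ac <- intersectionArea(ci, cj)
  if (ac == 0) return(zero)
  f <- function(ca, cb, n) {
    g <- contourGeometry(ca)
    pts <- cbind(g$px, g$py)
    pen <- insideContour(cb, pts)
    fo <- numeric(n)
    if (any(pen)) {
      # penetration depth: distance to cb's boundary
      pb <- contourPolygon(cb)
      d2 <- outer(g$px[pen], pb[, 1], "-")^2 + outer(g$py[pen], pb[, 2], "-")^2
      depth <- sqrt(apply(d2, 1, min))
      fo[pen] <- -wComp * depth
    }
    fo
  }
  list(energy = wComp * ac, area = ac, forceI = f(ci, cj, ni),
       forceJ = f(cj, ci, nj))
}

# rasterized intersection area of two star-shaped interiors (pixel counting
# over the overlap of the bounding boxes, integer pixel grid)
intersectionArea <- function(ci, cj) {
  ri <- max(ci@radii) * 1.3; rj <- max(cj@radii) * 1.3
  x0 <- floor(max(ci@pole[1] - ri, cj@pole[1] - rj))
  x1 <- ceiling(min(ci@pole[1] + ri, cj@pole[1] + rj))
  y0 <- floor(max(ci@pole[2] - ri, cj@pole[2] - rj))
  y1 <- ceiling(min(ci@pole[2] + ri, cj@pole[2] + rj))
  if (x1 < x0 || y1 < y0) return(0)
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  pts <- cbind(gx, gy)
  sum(insideContour(ci, pts) & insideContour(cj, pts))
}

#' Combined regularization forces for one contour
#'
#' Weighted sum of the curvature, area-range, area-stability, proximity and
#' overlap gradients against a set of frozen neighbor contours:
#' \eqn{E_r = w_\kappa E_\kappa + w_A E_A + w_{AS} E_{AS} +
#' E_{dist}(i,j) + E_{overlap}(i,j)} summed over neighbors j.
#'
#' @param contour the evolving \linkS4class{PolarContour}.
#' @param neighbors list of neighbor \linkS4class{PolarContour}s (frozen).
#' @param prevArea previous-frame area (NULL on the first frame).
#' @param config an \code{\link{energyConfig}}.
#' @return list of per-node force vectors (\code{curvature}, \code{area},
#'   \code{areaStab}, \code{proximity}, \code{overlap}, \code{total};
#'   positive = outward) and the total regularization \code{energy}.
#' @export
totalRegularization <- function(contour, neighbors = list(), prevArea = NULL,
                                config = energyConfig()) {
  n <- length(contour@radii)
  th <- nodeAngles(contour)
  dth <- 2 * pi / n
  A <- contourArea(contour)

  cg <- curvatureGradient(contour)
  fK <- -config$wKappa * cg$gradient            # outward at concave nodes
  eK <- config$wKappa * cg$energy

  # area range: quadratic energy whose dE/dA magnitude equals the printed
  # gradient; dA/dr_k ~ r_k * dtheta; NA bounds are inactive
  aMin <- if (is.finite(config$areaMin)) config$areaMin else 0
  aMax <- if (is.finite(config$areaMax)) config$areaMax else Inf
  dEdA <- -pmax(aMin - A, 0) + pmax(A - aMax, 0)
  eA <- config$wArea * 0.5 * (pmax(aMin - A, 0)^2 + pmax(A - aMax, 0)^2)
  fA <- -config$wArea * dEdA * contour@radii * dth

  eAS <- 0; fAS <- numeric(n)
  if (!is.null(prevArea) && is.finite(prevArea)) {
    eAS <- config$wAreaStab * areaStability(A, prevArea)
    fAS <- rep(-config$wAreaStab * sign(A - prevArea) / prevArea, n) *
      contour@radii * dth
  }

  fP <- numeric(n); fO <- numeric(n); eP <- 0; eO <- 0
  doProx <- config$dThresh > 0
  doOv <- config$wComp > 0
  if (doProx || doOv) for (nb in neighbors) {
    if (sqrt(sum((contour@pole - nb@pole)^2)) >
        max(contour@radii) + max(nb@radii) + config$dThresh + 4) next
    pp <- NULL
    if (doProx) {
      pp <- proximityPenalty(contour, nb, config$dThresh)
      act <- pp$penalty > 0
      fP[act] <- fP[act] + pp$radial[act]
      eP <- eP + pp$energy
    }
    if (doOv) {
      # when every node of this contour stays clearly outside the neighbor,
      # the interiors cannot intersect materially: skip the rasterization
      if (!is.null(pp) && min(pp$psi) > 1) next
      ov <- overlapPenalty(contour, nb, config$wComp)
      fO <- fO + ov$forceI
      eO <- eO + ov$energy
    }
  }

  total <- fK + fA + fAS + fP + fO
  list(curvature = fK, area = fA, areaStab = fAS, proximity = fP,
       overlap = fO, total = total,
       energy = eK + eA + eAS + eP + eO,
       energies = c(curvature = eK, area = eA, areaStab = eAS,
                    proximity = eP, overlap = eO))
}
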