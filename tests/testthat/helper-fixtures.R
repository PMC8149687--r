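# Synthetic image fixtures built in code, and independent oracle helpers.

# bright disk on dark background (values in [0, 1])
mkDisk <- function(h = 80, w = 80, cx = 40, cy = 40, r = 20,
                   fg = 100, bg = 20, noiseSd = 0) {
  gx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  gy <- matrix(0:(h - 1), h, w)
  img <- ifelse((gx - cx)^2 + (gy - cy)^2 <= r^2, fg, bg)
  if (noiseSd > 0) img <- img + matrix(rnorm(h * w, 0, noiseSd), h, w)
  img / 100
}

# ring cell: dark nucleus, bright cytoplasm, dark background
mkRing <- function(h = 64, w = 64, cx = 32, cy = 32, rNuc = 6, rCyt = 14,
                   nucV = 25, cytV = 100, bg = 20, noiseSd = 0) {
  gx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  gy <- matrix(0:(h - 1), h, w)
  d2 <- (gx - cx)^2 + (gy - cy)^2
  img <- ifelse(d2 <= rNuc^2, nucV, ifelse(d2 <= rCyt^2, cytV, bg))
  if (noiseSd > 0) img <- img + matrix(rnorm(h * w, 0, noiseSd), h, w)
  img / 100
}

# initialization ellipses from scene ground truth (the "user" of the tests)
truthEllipses <- function(truth, factor = 1.2) {
  nc <- length(truth@shapes)
  data.frame(cell_id = seq_len(nc),
             cx = sapply(truth@centers, function(m) m[1, 1]),
             cy = sapply(truth@centers, function(m) m[1, 2]),
             a = sapply(truth@shapes, function(s) mean(s$radii)) * factor,
             b = sapply(truth@shapes, function(s) mean(s$radii)) * factor,
             angle_deg = 0)
}

# per-frame per-cell IoU matrix of a tracking result against scene truth
trackIoUs <- function(tracks, truth) {
  nf <- truth@nFrames
  res <- sapply(seq_len(nf), function(t) sapply(seq_along(tracks), function(i) {
    cell <- trackContour(tracks[[i]], t)
    if (is(cell, "DoubleContour")) cell <- cell@cytoplasm
    iouScore(contourMask(cell, truth@dim), truthMask(truth, t, i, "cell"))
  }))
  matrix(res, nrow = length(tracks))       # cells x frames, even for one cell
}

# Independent textbook piecewise closed forms of the centered uniform
# B-splines (different derivation than the package's divided-difference
# formula); used as brute-force evaluation oracles.
refBasis2 <- function(x) {
  a <- abs(x)
  ifelse(a <= 0.5, 0.75 - x^2, ifelse(a <= 1.5, 0.5 * (1.5 - a)^2, 0))
}
refBasis3 <- function(x) {
  a <- abs(x)
  ifelse(a <= 1, 2 / 3 - x^2 + a^3 / 2, ifelse(a <= 2, (2 - a)^3 / 6, 0))
}

# full periodic summation over every coefficient and every wrap image
refEvalRadius <- function(coef, degree, angles) {
  n <- length(coef)
  h <- 2 * pi / n
  basis <- if (degree == 2) refBasis2 else refBasis3
  vapply(angles, function(th) {
    t <- (th / h) %% n
    s <- 0
    for (k in 0:(n - 1)) for (wrap in c(-n, 0, n))
      s <- s + coef[k + 1] * basis(t - k - wrap)
    s
  }, numeric(1))
}

# pixel-counting area oracle over a dense polygon (independent PIP via mgcv)
rasterArea <- function(poly, pad = 2) {
  x0 <- floor(min(poly[, 1])) - pad; x1 <- ceiling(max(poly[, 1])) + pad
  y0 <- floor(min(poly[, 2])) - pad; y1 <- ceiling(max(poly[, 2])) + pad
  xs <- x0:x1; ys <- y0:y1
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  bnd <- rbind(poly, poly[1, ])
  sum(mgcv::in.out(bnd, pts))
}
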