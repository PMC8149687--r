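## Uniform symmetric (cardinal) B-splines on a periodic knot grid.
##
## The radius function of a contour is r(theta) = sum_k c[k] beta^d(theta/h - k)
## with h = 2*pi/N and the coefficient index k wrapped modulo N, so the
## representation is 2*pi-periodic by construction.

#' Uniform symmetric B-spline basis function
#'
#' Evaluates the centered cardinal B-spline \eqn{\beta^d(x)} of degree
#' \code{degree}, supported on \eqn{[-(d+1)/2, (d+1)/2]}.  At the support
#' endpoints of the degree-0 box the symmetric convention
#' \eqn{\beta^0(\pm 1/2) = 1/2} is used so that derivative stencils of
#' higher-degree splines are symmetric.
#'
#' @param x numeric vector of evaluation points.
#' @param degree non-negative integer degree.
#' @return numeric vector of basis values.
#' @examples
#' bsplineBasis(0, 2)            # 3/4
#' bsplineBasis(c(-1, 0, 1), 2)  # 1/8 3/4 1/8
#' @export
bsplineBasis <- function(x, degree) {
  degree <- as.integer(degree)
  stopifnot(degree >= 0L)
  if (degree == 0L) {
    v <- as.numeric(abs(x) < 0.5)
    v[abs(abs(x) - 0.5) < 1e-12] <- 0.5
    return(v)
  }
  a <- abs(x)
  if (degree == 1L) return(pmax(1 - a, 0))
  if (degree == 2L) {
    # piecewise closed form, branch-free
    inner <- a <= 0.5
    mid <- a <= 1.5
    return(inner * (0.75 - x * x) + (mid & !inner) * 0.5 * (1.5 - a)^2)
  }
  if (degree == 3L) {
    inner <- a <= 1
    mid <- a <= 2
    return(inner * (2 / 3 - x * x + a^3 / 2) + (mid & !inner) * (2 - a)^3 / 6)
  }
  # general divided-difference formula
  v <- numeric(length(x))
  s <- x + (degree + 1) / 2
  for (j in 0:(degree + 1)) {
    t <- pmax(s - j, 0)
    v <- v + (-1)^j * choose(degree + 1, j) * t^degree
  }
  v / factorial(degree)
}

# first derivative of beta^d (degree >= 1)
bsplineBasisD1 <- function(x, degree) {
  bsplineBasis(x + 0.5, degree - 1L) - bsplineBasis(x - 0.5, degree - 1L)
}

# second derivative of beta^d (degree >= 2)
bsplineBasisD2 <- function(x, degree) {
  bsplineBasisD1(x + 0.5, degree - 1L) - bsplineBasisD1(x - 0.5, degree - 1L)
}

# Inverse of the N x N periodic collocation matrix M[i,k] = beta^d(i - k mod N),
# cached per (N, degree).  Solving M c = r yields interpolating coefficients.
periodicFitMatrix <- function(n, degree) {
  key <- paste0("fit_", n, "_", degree)
  inv <- get0(key, envir = .beas_cache)
  if (!is.null(inv)) return(inv)
  i <- 0:(n - 1)
  d <- outer(i, i, "-")
  d <- ((d + n / 2) %% n) - n / 2          # wrap to (-n/2, n/2]
  M <- bsplineBasis(d, degree)
  inv <- tryCatch(solve(M), error = function(e)
    stop("singular periodic B-spline interpolation system (N=", n,
         ", degree=", degree, ")", call. = FALSE))
  assign(key, inv, envir = .beas_cache)
  inv
}

#' Fit periodic interpolating B-spline coefficients
#'
#' Solves the periodic interpolation problem so that the spline evaluated at
#' the regular node angles reproduces \code{nodeRadii} exactly (round-trip
#' error below 1e-6).  For degree 1 the coefficients equal the radii.
#'
#' @param nodeRadii positive numeric vector of node radii (length N >= 8).
#' @param degree spline degree (default 2).
#' @return numeric vector of N coefficients.
#' @export
fitCoefficients <- function(nodeRadii, degree = 2L) {
  if (any(!is.finite(nodeRadii)) || any(nodeRadii <= 0))
    stop("node radii must be positive and finite")
  n <- length(nodeRadii)
  if (degree == 1L) return(as.numeric(nodeRadii))
  as.numeric(periodicFitMatrix(n, degree) %*% nodeRadii)
}

# Evaluate the periodic spline (and optionally derivatives w.r.t. theta) at
# arbitrary angles. Returns a list with r, and dr/dtheta, d2r/dtheta2 when asked.
splineEval <- function(coef, degree, angles, derivatives = 0L) {
  n <- length(coef)
  h <- 2 * pi / n
  t <- (angles / h) %% n                     # position in knot units, in [0, n)
  half <- (degree + 1) / 2
  k0 <- floor(t - half)
  r <- numeric(length(t))
  d1 <- if (derivatives >= 1L) numeric(length(t)) else NULL
  d2 <- if (derivatives >= 2L) numeric(length(t)) else NULL
  for (j in 0:(degree + 1)) {
    k <- k0 + j
    u <- t - k
    ck <- coef[(k %% n) + 1]
    r <- r + ck * bsplineBasis(u, degree)
    if (derivatives >= 1L) d1 <- d1 + ck * bsplineBasisD1(u, degree)
    if (derivatives >= 2L) d2 <- d2 + ck * bsplineBasisD2(u, degree)
  }
  out <- list(r = r)
  if (derivatives >= 1L) out$d1 <- d1 / h
  if (derivatives >= 2L) out$d2 <- d2 / h^2
  out
}
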