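## Configuration constructors.  Plain validated lists; serialized to/from the
## `energy:`, `descent:` and `scene:` sections of a YAML run config.

#' Energy configuration
#'
#' Weights and scales of the contour energies.  \code{rho} is the neighborhood
#' radius: the half-extent (in pixels, samples on each side of a node) of the
#' normal band in which local inside/outside means are estimated; it bounds the
#' per-frame motion the tracker can follow and should stay slightly smaller
#' than the cell radius.  \code{wKappa}, \code{wArea}, \code{wAreaStab} weight
#' the curvature, area-range and area-stability penalties; \code{wComp} is the
#' overlap (cell competition) weight and \code{dThresh} the minimal allowed
#' node-to-neighbor distance of the proximity penalty.  \code{areaMin} and
#' \code{areaMax} bound the contour area in px^2.  \code{marginDC} is the
#' radial nucleus-cytoplasm separation enforced in double-contour mode.
#'
#' @param rho neighborhood radius, px (>= 1; default 8).
#' @param wKappa curvature weight (default 0.5).
#' @param wArea area-range weight (default 1e-3).
#' @param wAreaStab area-stability weight (default 0.5).
#' @param wComp overlap-penalty weight w_c (default 0.02).
#' @param dThresh minimal distance d_T, px (default 1).
#' @param areaMin,areaMax area bounds, px^2.  The default NA derives
#'   per-cell bounds from each cell's initialization ellipse
#'   (0.55 and 1.3 times the ellipse area): the drawn ellipse is the user's
#'   statement of the cell's size, and the bounds keep a contour from being
#'   squeezed out of - or ballooning over - its cell where neighboring cells
#'   present no intensity border.
#' @param marginDC double-contour radial margin, px (default 1).
#' @param rhoGuard pole-exclusion radius (px) for the inside band samples of
#'   the outer contour: samples never come closer to the pole than this, so a
#'   dark nucleus cannot capture the inside statistics.  0 disables it; the
#'   initialization derives a per-cell value (half the ellipse radius) when
#'   tracking from ellipses.
#' @param smoothSigma Gaussian sigma (px) of the internal frame smoothing
#'   applied before energy evaluation; stabilizes the localized means against
#'   sensor noise.  When it exceeds 1 the descent runs coarse-to-fine: a
#'   refinement stage at sigma = 1 follows the coarse stage.  Signals are
#'   always extracted from the raw frames.  0 disables smoothing
#'   (default 2.5).
#' @return a validated list of class \code{"EnergyConfig"}.
#' @export
energyConfig <- function(rho = 8, wKappa = 0.5, wArea = 1e-3, wAreaStab = 0.5,
                         wComp = 0.02, dThresh = 1, areaMin = NA_real_,
                         areaMax = NA_real_, marginDC = 1, rhoGuard = 0,
                         smoothSigma = 2.5) {
  cfg <- list(rho = rho, wKappa = wKappa, wArea = wArea,
              wAreaStab = wAreaStab, wComp = wComp, dThresh = dThresh,
              areaMin = areaMin, areaMax = areaMax, marginDC = marginDC,
              rhoGuard = rhoGuard, smoothSigma = smoothSigma)
  if (cfg$rho < 1) stop("rho must be >= 1")
  if (cfg$smoothSigma < 0) stop("smoothSigma must be >= 0")
  if (is.finite(cfg$areaMin) && is.finite(cfg$areaMax) &&
      cfg$areaMin >= cfg$areaMax) stop("areaMin must be < areaMax")
  w <- c(cfg$wKappa, cfg$wArea, cfg$wAreaStab, cfg$wComp)
  if (any(w < 0) || cfg$marginDC < 0 || cfg$dThresh < 0)
    stop("weights, margin and dThresh must be >= 0")
  structure(cfg, class = "EnergyConfig")
}

#' Descent configuration
#'
#' Controls of the modified gradient descent with feedback step adjustment:
#' after an energy-decreasing (accepted) step the step size is multiplied by
#' \code{stepUp}; an energy-increasing step is reverted and the step is
#' multiplied by \code{stepDown}.  Evolution stops when the maximal node
#' displacement of an accepted step falls below \code{tolerance} or after
#' \code{maxIterations}.  \code{outerSweeps} is the number of rounds of
#' sequential per-cell updates within one frame.
#'
#' @param initialStep initial step, px (default 0.5).
#' @param stepUp multiplier > 1 (default 1.1).
#' @param stepDown multiplier in (0, 1) (default 0.5).
#' @param maxIterations iteration cap per contour per frame (default 100).
#' @param tolerance convergence displacement, px (default 0.05).
#' @param outerSweeps per-frame sweeps over the cells (default 2).
#' @return a validated list of class \code{"DescentConfig"}.
#' @export
descentConfig <- function(initialStep = 0.5, stepUp = 1.1, stepDown = 0.5,
                          maxIterations = 100L, tolerance = 0.05,
                          outerSweeps = 2L) {
  cfg <- list(initialStep = initialStep, stepUp = stepUp, stepDown = stepDown,
              maxIterations = as.integer(maxIterations), tolerance = tolerance,
              outerSweeps = as.integer(outerSweeps))
  if (cfg$maxIterations < 1) stop("maxIterations must be >= 1")
  if (cfg$tolerance <= 0) stop("tolerance must be > 0")
  if (cfg$stepUp <= 1 || cfg$stepDown <= 0 || cfg$stepDown >= 1)
    stop("stepUp must be > 1 and stepDown in (0, 1)")
  structure(cfg, class = "DescentConfig")
}
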