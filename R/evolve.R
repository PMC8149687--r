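## Per-frame energy minimization: modified gradient descent with feedback
## step-adjustment, for single contours and coupled double contours.

outerLayer <- function(x) if (is(x, "DoubleContour")) x@cytoplasm else x

# Pre-smoothed versions of a frame for the energy computation: a coarse level
# at config$smoothSigma and, when that sigma exceeds 1, a fine level at
# sigma = 1 used for a refinement stage (coarse-to-fine descent).  Prepping is
# idempotent so segmentFrame can do it once per frame.
prepEnergyFrames <- function(image, config) {
  if (inherits(image, "beasFrames")) return(image)
  s <- config$smoothSigma
  coarse <- if (s > 0) as.matrix(EBImage::gblur(image, sigma = s)) else image
  fine <- if (s > 1) as.matrix(EBImage::gblur(image, sigma = 1)) else NULL
  structure(list(coarse = coarse, fine = fine), class = "beasFrames")
}

# total energy of one contour configuration (data + regularization)
contourEnergy <- function(image, contour, prevArea = NULL, neighbors = list(),
                          config = energyConfig(), forbidOverlap = FALSE) {
  dt <- dataTerm(image, contour, config$rho, rGuard = config$rhoGuard)
  A <- contourArea(contour)
  cg <- curvatureGradient(contour)
  aMin <- if (is.finite(config$areaMin)) config$areaMin else 0
  aMax <- if (is.finite(config$areaMax)) config$areaMax else Inf
  e <- dt$energy + config$wKappa * cg$energy +
    config$wArea * 0.5 * (pmax(aMin - A, 0)^2 + pmax(A - aMax, 0)^2) +
    config$wAreaStab * areaStability(A, prevArea)
  doProx <- config$dThresh > 0
  doOv <- config$wComp > 0 || forbidOverlap
  if (doProx || doOv) for (nb in neighbors) {
    if (sqrt(sum((contour@pole - nb@pole)^2)) >
        max(contour@radii) + max(nb@radii) + config$dThresh + 4) next
    pp <- NULL
    if (doProx) {
      pp <- proximityPenalty(contour, nb, config$dThresh)
      e <- e + pp$energy
    }
    if (doOv) {
      # clearly separated contours cannot overlap: skip the rasterization
      if (!is.null(pp) && min(pp$psi) > 1) next
      ov <- overlapPenalty(contour, nb, config$wComp)
      if (forbidOverlap && ov$area > 0) return(Inf)
      e <- e + ov$energy
    }
  }
  e
}

#' Evolve a single contour to an energy minimum
#'
#' Modified gradient descent with feedback step adjustment: node radii move
#' along the (normalized) total radial force; an accepted (energy
#' non-increasing) step multiplies the step size by \code{stepUp}, a rejected
#' step is reverted and multiplies it by \code{stepDown}.  Stops when the
#' maximal node displacement of an accepted step is below \code{tolerance} or
#' at \code{maxIterations}.  Radii are clamped to >= 1 px.
#'
#' @param image numeric matrix (height x width), the frame.
#' @param contour starting \linkS4class{PolarContour}.
#' @param prevArea previous-frame area for the area-stability term (NULL on
#'   the first frame).
#' @param neighbors frozen neighbor contours for the competition terms.
#' @param config an \code{\link{energyConfig}}.
#' @param descent a \code{\link{descentConfig}}.
#' @param forbidOverlap reject any step that overlaps a neighbor (used during
#'   initialization).
#' @return list with \code{contour}, \code{converged}, \code{energy},
#'   \code{iterations} and \code{status} ("tracked" or "degenerate").
#' @export
evolveContour <- function(image, contour, prevArea = NULL, neighbors = list(),
                          config = energyConfig(), descent = descentConfig(),
                          forbidOverlap = FALSE) {
  frames <- prepEnergyFrames(image, config)
  it1 <- if (is.null(frames$fine)) descent$maxIterations else
    ceiling(descent$maxIterations * 0.6)
  r <- evolveCore(frames$coarse, contour, prevArea, neighbors, config,
                  descent, forbidOverlap, it1)
  if (!is.null(frames$fine)) {
    left <- descent$maxIterations - r$iterations
    if (left >= 1) {
      r2 <- evolveCore(frames$fine, r$contour, prevArea, neighbors, config,
                       descent, forbidOverlap, left)
      r2$iterations <- r$iterations + r2$iterations
      r <- r2
    }
  }
  contour <- r$contour
  status <- if (mean(contour@radii <= 1 + 1e-9) > 0.5) "degenerate" else "tracked"
  list(contour = contour, converged = r$converged, energy = r$energy,
       iterations = r$iterations, status = status)
}

# one descent stage on a single (pre-smoothed) image
evolveCore <- function(image, contour, prevArea, neighbors, config, descent,
                       forbidOverlap, maxIter) {
  maxR <- max(dim(image))
  if (is.finite(config$areaMax))
    maxR <- min(maxR, 2.2 * sqrt(config$areaMax / pi))
  E <- contourEnergy(image, contour, prevArea, neighbors, config, forbidOverlap)
  step <- descent$initialStep
  converged <- FALSE
  it <- 0L
  flat <- 0L
  f <- NULL                      # force is reused across rejected steps
  while (it < maxIter) {
    it <- it + 1L
    if (is.null(f))
      f <- dataTerm(image, contour, config$rho,
                    rGuard = config$rhoGuard)$force +
        totalRegularization(contour, neighbors, prevArea, config)$total
    m <- max(abs(f))
    if (m < 1e-12) { converged <- TRUE; break }
    candR <- pmin(pmax(contour@radii + step * f / m, 1), maxR)
    cand <- polarContour(contour@pole, candR, contour@degree)
    Ec <- contourEnergy(image, cand, prevArea, neighbors, config, forbidOverlap)
    accept <- if (is.finite(E)) Ec <= E + 1e-12 else is.finite(Ec)
    if (accept) {
      disp <- max(abs(candR - contour@radii))
      # several accepted steps in a row that barely improve the energy mean
      # the contour is oscillating on a flat valley floor: stop
      flat <- if (is.finite(E) && E - Ec < 1e-6 * max(1, abs(E)))
        flat + 1L else 0L
      contour <- cand; E <- Ec; f <- NULL
      step <- min(step * descent$stepUp, 4)
      if (disp < descent$tolerance || flat >= 3L) { converged <- TRUE; break }
    } else {
      step <- step * descent$stepDown
      if (step < descent$tolerance / 8) { converged <- TRUE; break }
    }
  }
  list(contour = contour, converged = converged, energy = E, iterations = it)
}

#' Evolve a coupled double contour
#'
#' Both layers are updated in one descent loop on the summed energy: the
#' nucleus layer follows the dark-inside/bright-outside nucleus interface,
#' the cytoplasm layer the cell-background interface, and the regularization
#' and competition terms act on the cytoplasm layer (curvature on both).
#' After every step the coupling constraint
#' \eqn{r_{cyt}(\theta) \ge r_{nuc}(\theta) + margin} is enforced by
#' projecting the cytoplasm radii upward.
#'
#' @param image numeric matrix, the frame.
#' @param dc starting \linkS4class{DoubleContour}.
#' @param prevArea previous-frame cytoplasm area (or NULL).
#' @param neighbors frozen neighbor (cytoplasm) contours.
#' @inheritParams evolveContour
#' @return list with \code{dc}, \code{converged}, \code{energy},
#'   \code{iterations}, \code{status} and \code{lowContrast} (TRUE when the
#'   nucleus interface carries no usable contrast).
#' @export
evolveDouble <- function(image, dc, prevArea = NULL, neighbors = list(),
                         config = energyConfig(), descent = descentConfig(),
                         forbidOverlap = FALSE) {
  frames <- prepEnergyFrames(image, config)
  it1 <- if (is.null(frames$fine)) descent$maxIterations else
    ceiling(descent$maxIterations * 0.6)
  r <- evolveDoubleCore(frames$coarse, dc, prevArea, neighbors, config,
                        descent, forbidOverlap, it1)
  if (!is.null(frames$fine)) {
    left <- descent$maxIterations - r$iterations
    if (left >= 1) {
      r2 <- evolveDoubleCore(frames$fine, r$dc, prevArea, neighbors, config,
                             descent, forbidOverlap, left)
      r2$iterations <- r$iterations + r2$iterations
      r <- r2
    }
  }
  s <- bandStats(frames$coarse, r$dc@nucleus, config$rho,
                 outCap = r$dc@cytoplasm@radii - r$dc@nucleus@radii)
  ok <- s$nIn > 0 & s$nOut > 0
  lowContrast <- mean(abs(s$uIn[ok] - s$uOut[ok])) < 0.02
  status <- if (mean(r$dc@cytoplasm@radii <= 1 + 1e-9) > 0.5)
    "degenerate" else "tracked"
  list(dc = r$dc, converged = r$converged, energy = r$energy,
       iterations = r$iterations, status = status,
       lowContrast = isTRUE(lowContrast))
}

evolveDoubleCore <- function(image, dc, prevArea, neighbors, config, descent,
                             forbidOverlap, maxIter) {
  margin <- dc@margin
  maxR <- max(dim(image))
  if (is.finite(config$areaMax))
    maxR <- min(maxR, 2.2 * sqrt(config$areaMax / pi))
  # energy components, cached separately: the cytoplasm part (with its
  # competition terms) is expensive and only changes when the cytoplasm
  # moves; the nucleus data term is cheap but depends on both layers (its
  # outward band is capped by the ring width) and only rewards dark-inside
  # configurations
  nucData <- function(nuc, cyt) dataTerm(image, nuc, config$rho,
    outCap = cyt@radii - nuc@radii - margin, darkInside = TRUE)$energy
  nucCurv <- function(nuc) config$wKappa * curvatureGradient(nuc)$energy
  cytEnergy <- function(cyt) contourEnergy(image, cyt, prevArea, neighbors,
                                           config, forbidOverlap)
  nuc <- dc@nucleus; cyt <- dc@cytoplasm
  eCyt <- cytEnergy(cyt); eNd <- nucData(nuc, cyt); eNc <- nucCurv(nuc)
  E <- eCyt + eNd + eNc
  stepN <- stepC <- descent$initialStep
  converged <- FALSE
  it <- 0L
  # The cytoplasm layer settles first: its position defines the ring in
  # which the nucleus statistics live.  Once it converges the nucleus layer
  # joins; each layer keeps its own feedback-adjusted step size and its own
  # accept/reject on the summed energy.
  phase <- "cyt"
  cytActive <- TRUE
  stall <- 0L
  while (it < maxIter) {
    it <- it + 1L
    accepted <- FALSE
    cytDone <- !cytActive
    if (cytActive) {
      fc <- dataTerm(image, cyt, config$rho, rGuard = config$rhoGuard)$force +
        totalRegularization(cyt, neighbors, prevArea, config)$total
      mc <- max(abs(fc))
      if (mc < 1e-12) {
        cytDone <- TRUE; cytActive <- FALSE
      } else {
        rc <- pmin(pmax(cyt@radii + stepC * fc / mc, 1), maxR)
        rc <- pmax(rc, nuc@radii + margin)         # coupling projection
        candC <- polarContour(cyt@pole, rc, cyt@degree)
        eCytC <- cytEnergy(candC)
        eNdC <- nucData(nuc, candC)
        Ec <- eCytC + eNdC + eNc
        accept <- if (is.finite(E)) Ec <= E + 1e-12 else is.finite(Ec)
        if (accept) {
          accepted <- TRUE
          dispC <- max(abs(rc - cyt@radii))
          cyt <- candC; eCyt <- eCytC; eNd <- eNdC; E <- Ec
          stepC <- min(stepC * descent$stepUp, 4)
          if (dispC < descent$tolerance) { cytDone <- TRUE; cytActive <- FALSE }
        } else {
          stepC <- stepC * descent$stepDown
          if (stepC < descent$tolerance / 8) { cytDone <- TRUE; cytActive <- FALSE }
        }
      }
    }
    if (phase == "cyt") {
      if (cytDone) { phase <- "nuc"; stepN <- descent$initialStep }
      next
    }
    fn <- dataTerm(image, nuc, config$rho,
                   outCap = cyt@radii - nuc@radii - margin,
                   darkInside = TRUE)$force -
      config$wKappa * curvatureGradient(nuc)$gradient
    mn <- max(abs(fn))
    nucDone <- mn < 1e-12 || stepN < descent$tolerance / 8
    if (!nucDone) {
      rn <- pmin(pmax(nuc@radii + stepN * fn / mn, 1), maxR)
      rcp <- pmax(cyt@radii, rn + margin)          # push cytoplasm out if hit
      candN <- polarContour(nuc@pole, rn, nuc@degree)
      cytMoved <- !all(rcp == cyt@radii)
      candC <- if (cytMoved) polarContour(cyt@pole, rcp, cyt@degree) else cyt
      eCytC <- if (cytMoved) cytEnergy(candC) else eCyt
      eNdC <- nucData(candN, candC)
      eNcC <- nucCurv(candN)
      En <- eCytC + eNdC + eNcC
      accept <- if (is.finite(E)) En <= E + 1e-12 else is.finite(En)
      if (accept) {
        accepted <- TRUE
        dispN <- max(abs(rn - nuc@radii))
        nuc <- candN; cyt <- candC
        eCyt <- eCytC; eNd <- eNdC; eNc <- eNcC; E <- En
        stepN <- min(stepN * descent$stepUp, 4)
        if (cytMoved) cytActive <- TRUE
        if (dispN < descent$tolerance) nucDone <- TRUE
      } else stepN <- stepN * descent$stepDown
    }
    if (cytDone && nucDone) { converged <- TRUE; break }
    # neither layer can find an accepted move: the pair has stalled out
    stall <- if (accepted) 0L else stall + 1L
    if (phase == "nuc" && stall >= 3L) { converged <- TRUE; break }
  }
  list(dc = new("DoubleContour", nucleus = nuc, cytoplasm = cyt,
                margin = margin),
       converged = converged, energy = E, iterations = it)
}

# rigid-shift a cell (both layers of a double contour) without refitting
shiftCell <- function(cell, delta) {
  if (is(cell, "DoubleContour")) {
    n <- cell@nucleus; n@pole <- n@pole + delta
    c <- cell@cytoplasm; c@pole <- c@pole + delta
    new("DoubleContour", nucleus = n, cytoplasm = c, margin = cell@margin)
  } else {
    cell@pole <- cell@pole + delta
    cell
  }
}

# Joint translation of all cells before the per-cell sweeps: under tissue
# motion every cell moves coherently, and a common translation leaves all
# competition terms unchanged, so it can be found by descending the summed
# data energy alone.  Sequential per-cell updates cannot perform this move
# (each cell's leading edge is blocked by its still-unmoved neighbors).
alignCellPack <- function(image, cells, cfgs) {
  dataE <- function(cs) sum(vapply(seq_along(cs), function(i) {
    cell <- cs[[i]]
    if (is(cell, "DoubleContour"))
      dataTerm(image, cell@nucleus, cfgs[[i]]$rho)$energy +
        dataTerm(image, cell@cytoplasm, cfgs[[i]]$rho)$energy
    else dataTerm(image, cell, cfgs[[i]]$rho)$energy
  }, numeric(1)))
  pull <- function(cs) {
    v <- c(0, 0)
    for (i in seq_along(cs)) {
      ct <- outerLayer(cs[[i]])
      f <- dataTerm(image, ct, cfgs[[i]]$rho)$force
      th <- nodeAngles(ct)
      v <- v + c(sum(f * cos(th)), sum(f * sin(th)))
    }
    v
  }
  E <- dataE(cells)
  step <- 2
  for (it in 1:12) {
    v <- pull(cells)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) break
    cand <- lapply(cells, shiftCell, delta = step * v / nv)
    Ec <- dataE(cand)
    if (Ec < E) {
      cells <- cand; E <- Ec
    } else {
      step <- step / 2
      if (step < 0.25) break
    }
  }
  cells
}

# re-center a cell (single or double) to the centroid of its outer layer
recentreCell <- function(cell) {
  if (is(cell, "DoubleContour")) {
    poly <- contourPolygon(cell@cytoplasm)
    cen <- polygonCentroid(poly)
    if (!pointsInPolygon(rbind(cen), poly))
      stop(errorCondition("pole centroid outside contour",
                          class = c("beas_degenerate", "error")))
    cyt <- resampleToPole(cell@cytoplasm, cen)
    nuc <- resampleToPole(cell@nucleus, cen)
    rc <- pmax(cyt@radii, nuc@radii + cell@margin)
    new("DoubleContour", nucleus = nuc,
        cytoplasm = polarContour(cen, rc, cyt@degree), margin = cell@margin)
  } else {
    recentreAndResample(cell)
  }
}

#' Initialize contours on the first frame
#'
#' Evolves each user-supplied ellipse on the first frame to convergence;
#' overlap between contours is not allowed at this stage (any overlapping
#' move is rejected).  In double mode the nucleus layer starts at
#' \code{nucleusFraction} of the ellipse and evolves to the dark-bright
#' interface.
#'
#' @param firstFrame numeric matrix.
#' @param ellipses data.frame with columns cell_id, cx, cy, a, b, angle_deg.
#' @param mode "one_layer" or "double".
#' @param config an \code{\link{energyConfig}}.
#' @param descent a \code{\link{descentConfig}}.
#' @param nNodes contour nodes (default 32).
#' @param nucleusFraction initial nucleus/ellipse size ratio (default 0.5).
#' @return list of \linkS4class{PolarContour} or \linkS4class{DoubleContour},
#'   in cell-id order.
#' @export
initializeContours <- function(firstFrame, ellipses, mode = "one_layer",
                               config = energyConfig(),
                               descent = descentConfig(),
                               nNodes = 32L, nucleusFraction = 0.5) {
  stopifnot(is.data.frame(ellipses))
  firstFrame <- prepEnergyFrames(firstFrame, config)
  ellipses <- ellipses[order(ellipses$cell_id), , drop = FALSE]
  if (any(ellipses$a <= 0.5) || any(ellipses$b <= 0.5))
    stop("initialization ellipse has no interior pixels")
  ne <- nrow(ellipses)
  # per-cell area bounds from the drawn ellipse (the user's size prior)
  cfgs <- lapply(seq_len(ne), function(i) {
    ci <- config
    ae <- pi * ellipses$a[i] * ellipses$b[i]
    if (!is.finite(ci$areaMin)) ci$areaMin <- 0.55 * ae
    if (!is.finite(ci$areaMax)) ci$areaMax <- 1.3 * ae
    if (ci$rhoGuard <= 0)
      ci$rhoGuard <- 0.5 * sqrt(ellipses$a[i] * ellipses$b[i])
    ci
  })
  seeds <- lapply(seq_len(ne), function(i) {
    e <- ellipses[i, ]
    ang <- if ("angle_deg" %in% names(e)) e$angle_deg * pi / 180 else 0
    ell <- makeEllipseContour(c(e$cx, e$cy), c(e$a, e$b), ang, nNodes)
    if (mode == "double") {
      nuc <- polarContour(c(e$cx, e$cy),
                          pmax(ell@radii * nucleusFraction, 1.5), ell@degree)
      new("DoubleContour", nucleus = nuc, cytoplasm = ell,
          margin = config$marginDC)
    } else ell
  })
  # two passes: on the first, the raw ellipses of the not-yet-evolved cells
  # stand in as neighbors so no early cell claims a neighbor's territory
  out <- seeds
  # two passes: the first fits every contour to its cell under the normal
  # competition terms (the raw ellipses of the not-yet-evolved cells stand in
  # as neighbors); the second enforces the no-overlap initialization rule by
  # boosting the competition weight to an effectively prohibitive level and
  # trimming the residual overlaps
  for (pass in 1:2) {
    for (i in seq_len(ne)) {
      nbrs <- lapply(out[-i], outerLayer)
      icfg <- cfgs[[i]]
      if (pass == 2) icfg$wComp <- max(icfg$wComp * 50, 1)
      if (mode == "double") {
        res <- evolveDouble(firstFrame, out[[i]], NULL, nbrs, icfg, descent)
        out[[i]] <- res$dc
      } else {
        res <- evolveContour(firstFrame, out[[i]], NULL, nbrs, icfg, descent)
        out[[i]] <- res$contour
      }
      out[[i]] <- tryCatch(recentreCell(out[[i]]),
                           beas_degenerate = function(e) out[[i]])
    }
  }
  structure(out, configs = cfgs)
}

#' Segment one frame with contour competition
#'
#' Runs \code{outerSweeps} rounds of sequential per-cell evolution (cell-id
#' order, neighbors frozen at their current contours for the competition
#' terms); each cell is re-centered to its geometric centroid after its
#' evolution.
#'
#' @param image numeric matrix, the frame.
#' @param cells list of \linkS4class{PolarContour} or
#'   \linkS4class{DoubleContour} seeds.
#' @param prevAreas numeric vector of previous-frame areas (NA on frame 1).
#' @param config an \code{\link{energyConfig}}, or a list of one per cell
#'   (per-cell area bounds).
#' @param descent a \code{\link{descentConfig}}.
#' @return list with \code{cells}, \code{status}, \code{iterations}.
#' @export
segmentFrame <- function(image, cells, prevAreas = rep(NA_real_, length(cells)),
                         config = energyConfig(), descent = descentConfig()) {
  stopifnot(length(cells) >= 1)
  cfgs <- if (inherits(config, "EnergyConfig"))
    rep(list(config), length(cells)) else config
  stopifnot(length(cfgs) == length(cells))
  image <- prepEnergyFrames(image, cfgs[[1]])
  status <- rep("tracked", length(cells))
  iters <- integer(length(cells))
  if (length(cells) > 1) cells <- alignCellPack(image$coarse, cells, cfgs)
  for (sweep in seq_len(descent$outerSweeps)) {
    for (i in seq_along(cells)) {
      nbrs <- lapply(cells[-i], outerLayer)
      pa <- if (is.finite(prevAreas[i])) prevAreas[i] else NULL
      res <- if (is(cells[[i]], "DoubleContour")) {
        r <- evolveDouble(image, cells[[i]], pa, nbrs, cfgs[[i]], descent)
        list(cell = r$dc, status = r$status, it = r$iterations)
      } else {
        r <- evolveContour(image, cells[[i]], pa, nbrs, cfgs[[i]], descent)
        list(cell = r$contour, status = r$status, it = r$iterations)
      }
      iters[i] <- iters[i] + res$it
      if (res$status == "degenerate") {
        status[i] <- "degenerate"        # keep previous contour, frozen
        next
      }
      cells[[i]] <- tryCatch(recentreCell(res$cell),
                             beas_degenerate = function(e) {
                               status[i] <<- "degenerate"
                               cells[[i]]
                             })
    }
  }
  list(cells = cells, status = status, iterations = iters)
}
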