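## Ground-truthed synthetic Ca2+-imaging scenes: overlapping cells with bright
## cytoplasm and dark nucleus, frame-to-frame motion, Ca2+ transient
## waveforms, scheduled out-of-focus (Gaussian-blurred) frames and additive
## noise.  Ground truth is captured before noise.

#' Synthetic scene configuration
#'
#' Defaults reproduce the evaluation conditions the tracker is designed for:
#' 7 overlapping cells of radius 14 +/- 2 px with a dark nucleus (45% of the
#' cell radius), equal cytoplasm baselines, per-frame motion up to 3 px,
#' 2 out-of-focus frames per 50, and Gaussian noise at SNR ~ 5 over 100
#' frames.
#'
#' @param imageSize integer (height, width), default c(160, 160).
#' @param nCells number of cells (default 7).
#' @param radiusMean,radiusSd cell radius distribution, px (default 14, 2).
#' @param nucleusFraction nucleus/cell radius ratio (default 0.45).
#' @param cytIntensity,nucIntensity,background baseline intensities
#'   (defaults 100, 25, 20; arbitrary fluorescence units).
#' @param overlapFactor target fractional radial overlap of neighbor pairs:
#'   center distance = (r_i + r_j) * (1 - overlapFactor); 0 places all cells
#'   disjoint (default 0.15).
#' @param motion list(type = "tissue" | "random_walk" | "global_affine" |
#'   "none", amplitude = max per-frame displacement px, headingSd =
#'   random-walk heading change sd, jitter = per-cell jitter amplitude px
#'   ("tissue" only), rotation = per-frame global rotation rad, drift =
#'   per-frame global translation).  "tissue" (the default) moves all cells
#'   with one shared smooth random walk plus small independent per-cell
#'   jitter, the way packed cells ride a contracting tissue; "random_walk"
#'   moves every cell independently (a deliberately adversarial condition).
#' @param transients list(ratePerCell = expected transients per cell over the
#'   recording, amplitude, tauRise, tauDecay in frames).
#' @param blur list(sigma = Gaussian sigma px, per50 = blurred frames per 50
#'   frames) or list(frames = explicit indices, sigma).
#' @param noiseSd additive Gaussian noise sd; NULL derives it from
#'   \code{snr} as (cytIntensity - background)/snr.
#' @param snr signal-to-noise ratio used when \code{noiseSd} is NULL.
#' @param nFrames number of frames (default 100).
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return a list of class \code{"SceneConfig"}.
#' @export
sceneConfig <- function(imageSize = c(160L, 160L), nCells = 7L,
                        radiusMean = 14, radiusSd = 2,
                        nucleusFraction = 0.45, cytIntensity = 100,
                        nucIntensity = 25, background = 20,
                        overlapFactor = 0.15,
                        motion = list(type = "tissue", amplitude = 3,
                                      headingSd = 0.4, jitter = 0.5,
                                      rotation = 0.004, drift = c(0.8, 0.4)),
                        transients = list(ratePerCell = 2, amplitude = 60,
                                          tauRise = 2, tauDecay = 8),
                        blur = list(sigma = 4, per50 = 2),
                        noiseSd = NULL, snr = 5,
                        nFrames = 100L, seed = 1L) {
  cfg <- list(imageSize = as.integer(imageSize), nCells = as.integer(nCells),
              radiusMean = radiusMean, radiusSd = radiusSd,
              nucleusFraction = nucleusFraction,
              cytIntensity = cytIntensity, nucIntensity = nucIntensity,
              background = background, overlapFactor = overlapFactor,
              motion = motion, transients = transients, blur = blur,
              noiseSd = noiseSd, snr = snr, nFrames = as.integer(nFrames),
              seed = as.integer(seed))
  if (cfg$radiusMean <= 0 || cfg$nucleusFraction <= 0 ||
      cfg$nucleusFraction >= 1)
    stop("radii must be positive and nucleusFraction in (0, 1)")
  if (any(c(cfg$cytIntensity, cfg$nucIntensity, cfg$background) < 0))
    stop("intensities must be >= 0")
  structure(cfg, class = "SceneConfig")
}

# dense radius table lookup: angle grid index for arbitrary angles
.tableRadius <- function(radii, angles, tableAngles) {
  n <- length(tableAngles)
  idx <- round(angles / (2 * pi) * n) %% n + 1
  radii[idx]
}

#' Generate a synthetic scene with ground truth
#'
#' Renders smooth cell blobs (radially perturbed circles) with dark nuclei on
#' a constant background; the cytoplasm intensity of cell c at frame t is
#' baseline + waveform_c(t).  Overlapping structures blend by maximum
#' (projection: a pixel shows the brightest structure covering it).  Frames
#' on the blur schedule are Gaussian-blurred, then Gaussian noise is added;
#' ground truth (masks, waveforms, trajectories) reflects the pre-noise
#' geometry.
#'
#' @param config a \code{\link{sceneConfig}}.
#' @return list with \code{stack} (height x width x frames array) and
#'   \code{truth} (\linkS4class{SceneTruth}).
#' @export
generateScene <- function(config = sceneConfig()) {
  stopifnot(inherits(config, "SceneConfig"))
  set.seed(config$seed)
  h <- config$imageSize[1]; w <- config$imageSize[2]
  nc <- config$nCells; nf <- config$nFrames
  nTab <- 720L
  tabAng <- seq(0, 2 * pi, length.out = nTab + 1)[seq_len(nTab)]

  # cell shapes: base radius + low-order harmonic perturbation
  baseR <- pmax(config$radiusMean + config$radiusSd * rnorm(nc),
                config$radiusMean * 0.5)
  shapes <- lapply(seq_len(nc), function(i) {
    a2 <- runif(1, 0.02, 0.07); a3 <- runif(1, 0.02, 0.06)
    p2 <- runif(1, 0, 2 * pi); p3 <- runif(1, 0, 2 * pi)
    r <- baseR[i] * (1 + a2 * cos(2 * tabAng + p2) + a3 * cos(3 * tabAng + p3))
    list(radii = r, nucleusRadii = r * config$nucleusFraction)
  })

  # placement: sequential attachment to the existing cluster at the target
  # center distance; overlapFactor 0 spaces the cells strictly apart
  mult <- if (config$overlapFactor <= 0) 1.12 else 1 - config$overlapFactor
  marg <- max(baseR) + config$motion$amplitude * 2 + 2
  centers0 <- matrix(NA_real_, nc, 2)
  centers0[1, ] <- c(w / 2, h / 2)
  if (nc > 1) {
    for (k in 2:nc) {
      ok <- FALSE
      for (att in seq_len(1000)) {
        j <- sample.int(k - 1, 1)
        a <- runif(1, 0, 2 * pi)
        d <- (baseR[j] + baseR[k]) * mult
        cand <- centers0[j, ] + d * c(cos(a), sin(a))
        if (cand[1] < marg || cand[1] > w - marg ||
            cand[2] < marg || cand[2] > h - marg) next
        dd <- sqrt(rowSums((centers0[seq_len(k - 1), , drop = FALSE] -
                            matrix(cand, k - 1, 2, byrow = TRUE))^2))
        lo <- (baseR[seq_len(k - 1)] + baseR[k]) * mult * 0.97
        if (all(dd >= lo)) { centers0[k, ] <- cand; ok <- TRUE; break }
      }
      if (!ok)
        stop(errorCondition(
          "could not place cells at the requested overlap within 1000 attempts",
          class = c("beas_placement", "error")))
    }
  }

  # motion
  centers <- lapply(seq_len(nc), function(i) {
    m <- matrix(NA_real_, nf, 2); m[1, ] <- centers0[i, ]; m
  })
  transforms <- list()
  mo <- config$motion
  if (identical(mo$type, "tissue") && nf > 1) {
    # one shared smooth walk for the tissue; small independent jitter per cell
    jit <- if (is.null(mo$jitter)) 0.5 else mo$jitter
    head <- runif(1, 0, 2 * pi)
    shift <- c(0, 0)
    jheads <- runif(nc, 0, 2 * pi)
    for (t in 2:nf) {
      head <- head + rnorm(1, 0, mo$headingSd)
      st <- mo$amplitude * runif(1, 0.6, 1)
      cand <- shift + st * c(cos(head), sin(head))
      cen1 <- centers0[1, ] + cand
      if (cen1[1] < marg || cen1[1] > w - marg ||
          cen1[2] < marg || cen1[2] > h - marg) {
        head <- head + pi
        cand <- shift + st * c(cos(head), sin(head))
      }
      shift <- cand
      jheads <- jheads + rnorm(nc, 0, 0.8)
      for (i in seq_len(nc)) {
        cand <- centers0[i, ] + shift +
          jit * runif(1) * c(cos(jheads[i]), sin(jheads[i]))
        d <- cand - centers[[i]][t - 1, ]
        dn <- sqrt(sum(d^2))                 # respect the amplitude bound
        if (dn > mo$amplitude) cand <- centers[[i]][t - 1, ] +
            d * mo$amplitude / dn
        centers[[i]][t, ] <- cand
      }
    }
  } else if (identical(mo$type, "random_walk") && nf > 1) {
    for (i in seq_len(nc)) {
      head <- runif(1, 0, 2 * pi)
      for (t in 2:nf) {
        head <- head + rnorm(1, 0, mo$headingSd)
        st <- mo$amplitude * runif(1, 0.6, 1)
        cand <- centers[[i]][t - 1, ] + st * c(cos(head), sin(head))
        if (cand[1] < marg || cand[1] > w - marg ||
            cand[2] < marg || cand[2] > h - marg) {
          head <- head + pi
          cand <- centers[[i]][t - 1, ] + st * c(cos(head), sin(head))
        }
        centers[[i]][t, ] <- cand
      }
    }
  } else if (identical(mo$type, "global_affine") && nf > 1) {
    cen <- c(w / 2, h / 2)
    rot <- if (is.null(mo$rotation)) 0.004 else mo$rotation
    dr <- if (is.null(mo$drift)) c(0.8, 0.4) else mo$drift
    for (t in 2:nf) {
      co <- cos(rot); si <- sin(rot)
      M <- matrix(c(co, -si, si, co), 2, 2, byrow = TRUE)
      off <- cen - M %*% cen + dr
      transforms[[t - 1]] <- list(M = M, offset = as.numeric(off))
      for (i in seq_len(nc))
        centers[[i]][t, ] <- as.numeric(M %*% centers[[i]][t - 1, ] + off)
    }
  } else {
    for (i in seq_len(nc)) for (t in seq_len(nf)) centers[[i]][t, ] <- centers0[i, ]
  }

  # transient waveforms (double exponential), equal baselines
  tr <- config$transients
  wave <- matrix(config$cytIntensity, nf, nc)
  if (!is.null(tr) && tr$ratePerCell > 0 && nf > 5) {
    for (i in seq_len(nc)) {
      k <- min(max(1L, stats::rpois(1, tr$ratePerCell)), max(nf - 10, 1))
      onsets <- sort(sample.int(max(nf - 10, 1), k))
      for (on in onsets) {
        s <- seq_len(nf) - on
        up <- ifelse(s >= 0, (1 - exp(-s / tr$tauRise)) * exp(-s / tr$tauDecay), 0)
        wave[, i] <- wave[, i] + tr$amplitude * up
      }
    }
  }

  # blur schedule
  bl <- config$blur
  blurFrames <- integer()
  sigma <- 0
  if (!is.null(bl)) {
    sigma <- bl$sigma
    if (!is.null(bl$frames)) {
      blurFrames <- as.integer(bl$frames)
    } else if (!is.null(bl$per50) && bl$per50 > 0) {
      for (w0 in seq(1, nf, by = 50)) {
        hi <- min(w0 + 49, nf)
        nbl <- min(bl$per50, hi - w0 + 1)
        blurFrames <- c(blurFrames, sort(sample(seq(w0, hi), nbl)))
      }
    }
  }

  noiseSd <- if (!is.null(config$noiseSd)) config$noiseSd else
    (config$cytIntensity - config$background) / config$snr

  # render
  stack <- array(config$background, dim = c(h, w, nf))
  for (t in seq_len(nf)) {
    img <- matrix(config$background, h, w)
    for (i in seq_len(nc)) {
      ce <- centers[[i]][t, ]
      rmax <- max(shapes[[i]]$radii) + 1
      x0 <- max(0, floor(ce[1] - rmax)); x1 <- min(w - 1, ceiling(ce[1] + rmax))
      y0 <- max(0, floor(ce[2] - rmax)); y1 <- min(h - 1, ceiling(ce[2] + rmax))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - ce[1]
      gy <- matrix(ys, length(ys), length(xs)) - ce[2]
      th <- atan2(gy, gx) %% (2 * pi)
      rr <- sqrt(gx^2 + gy^2)
      rc <- .tableRadius(shapes[[i]]$radii, th, tabAng)
      rn <- .tableRadius(shapes[[i]]$nucleusRadii, th, tabAng)
      inCell <- rr <= rc
      inNuc <- rr <= rn
      val <- ifelse(inNuc, config$nucIntensity, wave[t, i])
      sub <- img[ys + 1, xs + 1]
      sub[inCell] <- pmax(sub[inCell], val[inCell])
      img[ys + 1, xs + 1] <- sub
    }
    if (t %in% blurFrames && sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = sigma))
    if (noiseSd > 0)
      img <- pmax(img + matrix(rnorm(h * w, 0, noiseSd), h, w), 0)
    stack[, , t] <- img
  }

  truth <- new("SceneTruth", dim = c(h, w), nFrames = nf, shapes = shapes,
               angles = tabAng, centers = centers, waveforms = wave,
               blurFrames = as.integer(blurFrames), transforms = transforms)
  list(stack = stack, truth = truth)
}

#' Ground-truth mask of one cell on one frame
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param frame frame index.
#' @param cell cell index.
#' @param type "cell" (whole cell), "nucleus", or "cytoplasm" (cell minus
#'   nucleus).
#' @return logical matrix (height x width).
#' @export
truthMask <- function(truth, frame, cell, type = c("cell", "nucleus", "cytoplasm")) {
  type <- match.arg(type)
  h <- truth@dim[1]; w <- truth@dim[2]
  ce <- truth@centers[[cell]][frame, ]
  sh <- truth@shapes[[cell]]
  m <- matrix(FALSE, h, w)
  rmax <- max(sh$radii) + 1
  x0 <- max(0, floor(ce[1] - rmax)); x1 <- min(w - 1, ceiling(ce[1] + rmax))
  y0 <- max(0, floor(ce[2] - rmax)); y1 <- min(h - 1, ceiling(ce[2] + rmax))
  if (x1 < x0 || y1 < y0) return(m)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - ce[1]
  gy <- matrix(ys, length(ys), length(xs)) - ce[2]
  th <- atan2(gy, gx) %% (2 * pi)
  rr <- sqrt(gx^2 + gy^2)
  rc <- .tableRadius(sh$radii, th, truth@angles)
  rn <- .tableRadius(sh$nucleusRadii, th, truth@angles)
  sel <- switch(type, cell = rr <= rc, nucleus = rr <= rn,
                cytoplasm = rr <= rc & rr > rn)
  m[ys + 1, xs + 1] <- sel
  m
}

#' Inject an artificial transient into a recording
#'
#' Adds (or multiplies in) a known waveform on the masked pixels of each
#' frame — the planted-peak validation device: a fully known signal embedded
#' in otherwise real complexity, later re-extracted and compared.
#'
#' @param stack numeric array (height x width x frames).
#' @param maskTrack list of logical masks, one per frame (the moving
#'   cytoplasm region).
#' @param waveform numeric vector, length = number of frames.
#' @param mode "additive" (default) or "multiplicative".
#' @return the modified stack.
#' @export
injectTransient <- function(stack, maskTrack, waveform,
                            mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stack <- asStack(stack)
  nf <- dim(stack)[3]
  stopifnot(length(maskTrack) == nf, length(waveform) == nf)
  for (t in seq_len(nf)) {
    m <- maskTrack[[t]]
    if (!any(m)) { warning("empty mask on frame ", t, "; frame skipped"); next }
    fr <- stack[, , t]
    fr[m] <- if (mode == "additive") fr[m] + waveform[t] else fr[m] * (1 + waveform[t])
    stack[, , t] <- fr
  }
  stack
}

#' Normalized root-mean-square error
#'
#' RMSE between a signal and its reference, divided by the reference's
#' dynamic range (max - min).
#'
#' @param signal,reference equal-length numeric vectors; the reference must
#'   not be constant.
#' @return scalar normalized RMSE.
#' @export
normalizedRMSE <- function(signal, reference) {
  stopifnot(length(signal) == length(reference))
  rng <- diff(range(reference))
  if (rng <= 0) stop("reference signal is constant; normalized RMSE undefined")
  sqrt(mean((signal - reference)^2)) / rng
}
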