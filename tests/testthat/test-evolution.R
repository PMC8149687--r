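# Per-frame evolution, double-contour coupling, multi-cell segmentation and
# the tracking loop.

test_that("a single contour converges onto a clean disk from either side", {
  disk <- mkDisk(r = 20)
  fromIn <- evolveContour(disk, polarContour(c(40, 40), rep(15, 32)))
  expect_true(fromIn$converged)
  expect_lt(mean(abs(nodeRadii(fromIn$contour) - 20)), 0.5)
  fromOut <- evolveContour(disk, polarContour(c(40, 40), rep(26, 32)))
  expect_lt(mean(abs(nodeRadii(fromOut$contour) - 20)), 0.5)
  # the final energy never exceeds the starting energy (feedback rule)
  start <- polarContour(c(40, 40), rep(15, 32))
  E0 <- beastrack:::contourEnergy(
    beastrack:::prepEnergyFrames(disk, energyConfig())$coarse, start)
  expect_lte(fromIn$energy, E0)
})

test_that("uniform image with zero regularization leaves the contour unchanged", {
  uni <- matrix(0.5, 80, 80)
  ct <- polarContour(c(40, 40), rep(12, 32))
  res <- evolveContour(uni, ct,
                       config = energyConfig(wKappa = 0, wArea = 0,
                                             wAreaStab = 0, wComp = 0,
                                             dThresh = 0))
  expect_equal(nodeRadii(res$contour), rep(12, 32), tolerance = 1e-9)
  expect_true(res$converged)
})

test_that("a single iteration applies at most one radius update", {
  disk <- mkDisk(r = 20)
  d1 <- descentConfig(maxIterations = 1L, tolerance = 100)
  res <- evolveContour(disk, polarContour(c(40, 40), rep(15, 32)),
                       descent = d1)
  expect_lte(res$iterations, 1L)
  expect_lte(max(abs(nodeRadii(res$contour) - 15)), d1$initialStep + 1e-9)
})

test_that("double contour recovers a ring cell and keeps the layer ordering", {
  ring <- mkRing(rNuc = 6, rCyt = 14)
  ell <- makeEllipseContour(c(32, 32), c(18, 18), 0, 32)
  dc <- new("DoubleContour", nucleus = polarContour(c(32, 32), nodeRadii(ell) * 0.5),
            cytoplasm = ell, margin = 1)
  res <- evolveDouble(ring, dc)
  expect_lt(abs(mean(nodeRadii(res$dc@nucleus)) - 6), 1)
  expect_lt(abs(mean(nodeRadii(res$dc@cytoplasm)) - 14), 1)
  expect_true(all(nodeRadii(res$dc@cytoplasm) >=
                    nodeRadii(res$dc@nucleus) + 1 - 1e-9))
  expect_false(res$lowContrast)
})

test_that("the coupling projection restores layer ordering immediately", {
  ring <- mkRing()
  nuc <- polarContour(c(32, 32), rep(8, 32))
  cyt <- polarContour(c(32, 32), rep(9.5, 32))   # thinner than nucleus + margin at some updates
  dc <- new("DoubleContour", nucleus = nuc, cytoplasm = cyt, margin = 1)
  res <- evolveDouble(ring, dc, descent = descentConfig(maxIterations = 3L))
  expect_true(all(nodeRadii(res$dc@cytoplasm) >=
                    nodeRadii(res$dc@nucleus) + 1 - 1e-9))
})

test_that("initialization keeps disjoint cells disjoint and fits a disk", {
  # disk with a 30% larger initialization ellipse
  disk <- mkDisk(r = 20)
  ell1 <- data.frame(cell_id = 1, cx = 40, cy = 40, a = 26, b = 26,
                     angle_deg = 0)
  init <- initializeContours(disk, ell1)
  expect_lt(mean(abs(nodeRadii(init[[1]]) - 20)), 0.5)
  # two disjoint disks -> converged contours disjoint
  two <- mkDisk(h = 80, w = 140, cx = 40, cy = 40, r = 15)
  gx <- matrix(0:139, 80, 140, byrow = TRUE); gy <- matrix(0:79, 80, 140)
  two[(gx - 100)^2 + (gy - 40)^2 <= 15^2] <- 1
  ell2 <- data.frame(cell_id = 1:2, cx = c(40, 100), cy = c(40, 40),
                     a = c(19, 19), b = c(19, 19), angle_deg = 0)
  init2 <- initializeContours(two, ell2)
  expect_equal(beastrack:::intersectionArea(init2[[1]], init2[[2]]), 0)
  expect_error(initializeContours(disk,
    data.frame(cell_id = 1, cx = 40, cy = 40, a = 0.2, b = 0.2,
               angle_deg = 0)), "interior")
})

test_that("the tracker is stationary on a static scene", {
  cfg <- sceneConfig(nCells = 2, nFrames = 10, overlapFactor = 0,
                     imageSize = c(96L, 96L),
                     motion = list(type = "none", amplitude = 0),
                     transients = NULL, blur = NULL, noiseSd = 4, seed = 5)
  sc <- generateScene(cfg)
  tk <- trackCells(sc$stack, truthEllipses(sc$truth))
  for (i in 1:2) {
    g1 <- contourPolygon(trackContour(tk[[i]], 1), 1L)
    gT <- contourPolygon(trackContour(tk[[i]], 10), 1L)
    expect_lt(mean(sqrt(rowSums((g1 - gT)^2))), 0.5)
  }
})

test_that("tracking follows a moving cell but loses it beyond the band range", {
  cfg <- sceneConfig(nCells = 1, nFrames = 10, overlapFactor = 0,
                     imageSize = c(120L, 120L),
                     motion = list(type = "random_walk", amplitude = 3,
                                   headingSd = 0.3),
                     transients = NULL, blur = NULL, seed = 8)
  sc <- generateScene(cfg)
  tk <- trackCells(sc$stack, truthEllipses(sc$truth))
  ious <- trackIoUs(tk, sc$truth)
  expect_gt(mean(ious), 0.7)
  # far beyond the band's detectable range: tracking collapses
  cfgFast <- sceneConfig(nCells = 1, nFrames = 8, overlapFactor = 0,
                         imageSize = c(300L, 300L),
                         motion = list(type = "random_walk", amplitude = 28,
                                       headingSd = 0.05),
                         transients = NULL, blur = NULL, seed = 8)
  scF <- generateScene(cfgFast)
  tkF <- trackCells(scF$stack, truthEllipses(scF$truth),
                    config = energyConfig(rho = 8))
  iouF <- trackIoUs(tkF, scF$truth)
  expect_lt(iouF[1, 8], 0.3)
})

test_that("out-of-focus frames do not break tracking", {
  # blur sigma = half the cell radius on two frames mid-recording
  cfg <- sceneConfig(nCells = 1, nFrames = 12, overlapFactor = 0,
                     imageSize = c(120L, 120L), radiusMean = 14, radiusSd = 0,
                     motion = list(type = "random_walk", amplitude = 2,
                                   headingSd = 0.3),
                     transients = NULL, blur = list(frames = c(6, 7), sigma = 7),
                     seed = 12)
  sc <- generateScene(cfg)
  tk <- trackCells(sc$stack, truthEllipses(sc$truth))
  ious <- trackIoUs(tk, sc$truth)
  expect_gt(min(ious[1, c(6, 7)]), 0.5)       # survives the blurred frames
  expect_gt(mean(ious[1, 9:12]), 0.7)         # and recovers afterwards
})

test_that("degenerate cells freeze their last valid contour", {
  # a cell whose image support vanishes after frame 2: contour must persist
  stack <- array(0.2, dim = c(64, 64, 4))
  stack[, , 1:2] <- mkRing(rNuc = 0, rCyt = 12)  # plain disk
  ell <- data.frame(cell_id = 1, cx = 32, cy = 32, a = 15, b = 15,
                    angle_deg = 0)
  tk <- trackCells(stack, ell)
  expect_length(trackStatus(tk[[1]]), 4)
  expect_s4_class(trackContour(tk[[1]], 4), "PolarContour")
})
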