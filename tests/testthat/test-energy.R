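# Data-attachment and regularization energies: bands, localized means, Yezzi
# forces, curvature/area/competition terms.

test_that("band pixels lie along the normal and respect the disk geometry", {
  circ <- polarContour(c(40, 40), rep(16, 32))
  b <- localBand(c(80, 80), circ, 1, 5)     # node 1 sits at angle 0
  expect_lte(nrow(b$inside), 5)
  expect_lte(nrow(b$outside), 5)
  # normal of a circle is radial: the bands lie on the +x ray through (56, 40)
  expect_true(all(b$inside[, 2] == 40))
  expect_true(all(b$outside[, 2] == 40))
  expect_true(all(b$inside[, 1] <= 56 & b$inside[, 1] >= 51))
  expect_true(all(b$outside[, 1] >= 56 & b$outside[, 1] <= 61))
  # all nodes: inside set within the disk, outside set disjoint from it
  for (k in seq(1, 32, by = 3)) {
    bk <- localBand(c(80, 80), circ, k, 5)
    din <- sqrt((bk$inside[, 1] - 40)^2 + (bk$inside[, 2] - 40)^2)
    dout <- sqrt((bk$outside[, 1] - 40)^2 + (bk$outside[, 2] - 40)^2)
    expect_true(all(din <= 16))
    expect_true(all(dout >= 16))
  }
})

test_that("localized means equal exhaustive per-pixel classification", {
  set.seed(21)
  img <- matrix(runif(80 * 80), 80, 80)
  circ <- polarContour(c(40, 40), rep(16, 32))
  for (k in c(1, 7, 19, 30)) {
    m <- localizedMeans(img, circ, k, 6)
    b <- localBand(dim(img), circ, k, 6)
    # oracle: scalar loop over the returned pixel sets
    sIn <- 0; sOut <- 0
    for (j in seq_len(nrow(b$inside)))
      sIn <- sIn + img[b$inside[j, 2] + 1, b$inside[j, 1] + 1]
    for (j in seq_len(nrow(b$outside)))
      sOut <- sOut + img[b$outside[j, 2] + 1, b$outside[j, 1] + 1]
    expect_identical(m$uIn, sIn / nrow(b$inside))
    expect_identical(m$uOut, sOut / nrow(b$outside))
  }
  # step image: contour on the edge recovers the two plateau values
  # (quarter-pixel center offset keeps sample rounding unambiguous)
  step <- mkDisk(cx = 40.25, cy = 40.25, r = 16, fg = 100, bg = 10)
  circq <- polarContour(c(40.25, 40.25), rep(16, 32))
  ms <- localizedMeans(step, circq, 1, 5)
  expect_equal(ms$uIn, 1.0)
  expect_equal(ms$uOut, 0.1)
  # uniform image
  mu <- localizedMeans(matrix(0.4, 80, 80), circ, 3, 5)
  expect_equal(mu$uIn, 0.4)
  expect_equal(mu$uOut, 0.4)
})

test_that("Yezzi force points toward the configuration of maximal separation", {
  # uniform image: zero force everywhere
  uni <- matrix(0.5, 80, 80)
  circ16 <- polarContour(c(40, 40), rep(16, 32))
  expect_equal(yezziForce(uni, circ16, 5, 8), 0)
  disk <- mkDisk(r = 20)
  # contour inside the disk: outward force at all nodes, and the direction
  # agrees with the numeric energy difference E(r) = sum -(uIn - uOut)^2
  Eof <- function(r) {
    ct <- polarContour(c(40, 40), rep(r, 32))
    -sum(vapply(1:32, function(k) {
      m <- localizedMeans(disk, ct, k, 8)
      (m$uIn - m$uOut)^2
    }, numeric(1)))
  }
  f16 <- vapply(1:32, function(k) yezziForce(disk, circ16, k, 8), numeric(1))
  expect_true(all(f16 > 0))
  expect_lt(Eof(17), Eof(16))              # expanding decreases the energy
  circ24 <- polarContour(c(40, 40), rep(24, 32))
  f24 <- vapply(1:32, function(k) yezziForce(disk, circ24, k, 8), numeric(1))
  expect_true(all(f24 < 0))
  expect_lt(Eof(23), Eof(24))              # shrinking decreases the energy
})

test_that("curvature gradient is active only at concavities", {
  circ <- polarContour(c(0, 0), rep(12, 32))
  cg <- curvatureGradient(circ)
  expect_equal(cg$gradient, rep(0, 32))
  expect_equal(cg$energy, 0)
  # single dent: gradient support near the dent, descent direction outward
  r <- rep(12, 32); r[9] <- 8
  dent <- polarContour(c(0, 0), r)
  cgd <- curvatureGradient(dent)
  expect_gt(cgd$energy, 0)
  expect_true(all(cgd$gradient <= 0))
  expect_lt(cgd$gradient[9], 0)
  expect_equal(max(abs(cgd$gradient[c(1:4, 15:32)])), 0, tolerance = 1e-9)
  # moving the dent node outward (descent direction) lowers the energy
  r2 <- r; r2[9] <- 8.5
  expect_lt(curvatureGradient(polarContour(c(0, 0), r2))$energy, cgd$energy)
})

test_that("area-range gradient reproduces the printed formula exactly", {
  expect_identical(areaGradient(200, 100, 400), 0)
  expect_identical(areaGradient(50, 100, 400), -50)
  expect_identical(areaGradient(500, 100, 400), -100)
})

test_that("area stability is the relative area change", {
  expect_identical(areaStability(100, 100), 0)
  expect_identical(areaStability(110, 100), 0.1)
  expect_identical(areaStability(90, 100), 0.1)
  expect_identical(areaStability(120, NULL), 0)   # first frame: inactive
})

test_that("proximity penalty follows the thresholded signed distance", {
  a <- polarContour(c(0, 0), rep(10, 32))
  bFar <- polarContour(c(40, 0), rep(10, 32))     # gap 20 px
  pp <- proximityPenalty(a, bFar, 5)
  expect_equal(pp$penalty, rep(0, 32))
  # node at distance 2 from the neighbor, d_T = 5 -> penalty 3
  bNear <- polarContour(c(22, 0), rep(10, 32))    # gap 2 at angle 0
  pn <- proximityPenalty(a, bNear, 5)
  expect_equal(pn$penalty[1], 3, tolerance = 0.1)
  expect_lt(pn$psi[1] - 2, 0.1)
  # brute-force node-to-dense-polygon distances
  set.seed(9)
  c1 <- polarContour(c(0, 0), runif(32, 8, 12))
  c2 <- polarContour(c(18, 5), runif(32, 8, 12))
  pb <- proximityPenalty(c1, c2, 50)
  poly2 <- contourPolygon(c2)
  g1 <- contourPolygon(c1, 1L)                    # the 32 nodes themselves
  for (k in c(1, 5, 17, 29)) {
    dmin <- min(sqrt((g1[k, 1] - poly2[, 1])^2 + (g1[k, 2] - poly2[, 2])^2))
    expect_lt(abs(abs(pb$psi[k]) - dmin), 0.5)
  }
})

test_that("overlap penalty is w_c times the intersection area, zero when disjoint", {
  a <- polarContour(c(0, 0), rep(10, 32))
  bFar <- polarContour(c(40, 0), rep(10, 32))
  od <- overlapPenalty(a, bFar, 0.5)
  expect_identical(od$energy, 0)
  expect_equal(od$forceI, rep(0, 32))
  # identical circles: energy = w_c * A
  oi <- overlapPenalty(a, polarContour(c(0, 0), rep(10, 32)), 0.5)
  expect_lt(abs(oi$energy - 0.5 * pi * 100) / (0.5 * pi * 100), 0.05)
  # two r=10 circles 10 px apart: lens area closed form
  b10 <- polarContour(c(10, 0), rep(10, 32))
  lens <- 2 * 100 * acos(5 / 10) - 5 * sqrt(4 * 100 - 100)
  ov <- overlapPenalty(a, b10, 1)
  # unit-pixel counting of a ~120 px^2 lens carries a few percent granularity
  expect_lt(abs(ov$area - lens) / lens, 0.05)
  # symmetry of the energy
  ov2 <- overlapPenalty(b10, a, 1)
  expect_equal(ov$energy, ov2$energy, tolerance = 0.02 * ov$energy)
  # penetrating nodes feel an inward force
  expect_true(any(ov$forceI < 0))
  expect_true(all(ov$forceI <= 0))
})

test_that("competition terms are translation invariant", {
  a <- polarContour(c(0, 0), rep(10, 32))
  b <- polarContour(c(15, 3), rep(9, 32))
  sh <- c(7.3, -4.1)
  a2 <- polarContour(c(0, 0) + sh, rep(10, 32))
  b2 <- polarContour(c(15, 3) + sh, rep(9, 32))
  e1 <- overlapPenalty(a, b, 1)$energy
  e2 <- overlapPenalty(a2, b2, 1)$energy
  expect_lt(abs(e1 - e2), max(0.05 * e1, 3))   # within rasterization jitter
  p1 <- proximityPenalty(a, b, 6)$energy
  p2 <- proximityPenalty(a2, b2, 6)$energy
  expect_lt(abs(p1 - p2), 0.2)
})

test_that("total regularization adds the individual terms", {
  cfg <- energyConfig(wKappa = 0.7, wArea = 1e-3, wAreaStab = 0.5,
                      wComp = 0.1, dThresh = 4, areaMin = 200, areaMax = 280)
  set.seed(13)
  ct <- polarContour(c(0, 0), runif(32, 9, 11))
  nb <- polarContour(c(16, 2), rep(10, 32))
  tot <- totalRegularization(ct, list(nb), prevArea = 290, config = cfg)
  expect_equal(tot$total,
               tot$curvature + tot$area + tot$areaStab +
                 tot$proximity + tot$overlap)
  expect_true(all(is.finite(tot$total)))
  expect_equal(tot$energy, sum(tot$energies))
  # all weights zero, no neighbors: zero forces
  z <- totalRegularization(polarContour(c(0, 0), rep(10, 32)), list(), NULL,
                           energyConfig(wKappa = 0, wArea = 0, wAreaStab = 0,
                                        wComp = 0, dThresh = 0))
  expect_equal(z$total, rep(0, 32))
  expect_equal(z$energy, 0)
  # isolated circle within its area bounds: only curvature evaluated, = 0
  iso <- totalRegularization(polarContour(c(0, 0), rep(10, 32)), list(), NULL,
                             energyConfig(areaMin = 100, areaMax = 500))
  expect_equal(iso$total, rep(0, 32), tolerance = 1e-9)
})
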