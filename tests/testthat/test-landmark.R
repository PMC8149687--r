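# Landmark-based geometric transforms and ROI propagation.

test_that("identical point sets yield the identity transform", {
  set.seed(41)
  p <- cbind(runif(8, 0, 100), runif(8, 0, 100))
  tf <- estimateFrameTransform(p, p, "affine")
  expect_equal(tf@rms, 0, tolerance = 1e-9)
  expect_lt(max(abs(applyTransform(tf, p) - p)), 1e-9)
})

test_that("pure translation is recovered exactly", {
  set.seed(43)
  p <- cbind(runif(6, 0, 80), runif(6, 0, 80))
  q <- sweep(p, 2, c(3, -2), "+")
  tf <- estimateFrameTransform(p, q, "translation")
  expect_equal(unname(tf@params[1, ]), c(3, -2), tolerance = 1e-12)
  expect_equal(tf@rms, 0, tolerance = 1e-12)
})

test_that("a known affine map is recovered to machine precision, noise gives rms ~ sigma", {
  set.seed(47)
  p <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  A <- matrix(c(1.05, -0.1, 0.08, 0.97), 2, 2)
  b <- c(4, -7)
  q <- t(A %*% t(p) + b)
  tf <- estimateFrameTransform(p, q, "affine")
  expect_lt(max(abs(applyTransform(tf, p) - q)), 1e-9)
  # the fitted solution is the least-squares optimum: perturbations hurt
  obj <- function(params) sum((q - transformDesignTest(p) %*% params)^2)
  transformDesignTest <- function(x) cbind(x[, 1], x[, 2], 1)
  base <- obj(tf@params)
  for (k in 1:5) {
    pert <- tf@params + matrix(rnorm(6, 0, 1e-3), 3, 2)
    expect_gt(obj(pert), base)
  }
  # gaussian landmark noise of 0.5 px leaves a residual of about 0.5 px
  rms <- replicate(20, {
    qn <- q + matrix(rnorm(20, 0, 0.5), 10, 2)
    estimateFrameTransform(p, qn, "affine")@rms
  })
  expect_lt(abs(mean(rms) - 0.5), 0.2)
})

test_that("degree-2 polynomial motion needs the richer model", {
  set.seed(53)
  p <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  q <- cbind(2 + p[, 1] + 0.002 * p[, 1]^2 - 0.001 * p[, 1] * p[, 2],
             -1 + p[, 2] + 0.003 * p[, 2]^2)
  tf2 <- estimateFrameTransform(p, q, "polynomial-2")
  expect_lt(tf2@rms, 1e-9)
  expect_gt(estimateFrameTransform(p, q, "affine")@rms, 1e-3)
})

test_that("an under-determined fit falls back to a simpler model", {
  p <- cbind(c(10, 20), c(5, 5))
  q <- sweep(p, 2, c(1, 1), "+")
  expect_warning(tf <- estimateFrameTransform(p, q, "affine"),
                 "fell back")
  expect_identical(tf@model, "translation")
  # collinear landmarks are rank-deficient for affine... but 3 collinear
  # points still solve the translation exactly
  p3 <- cbind(c(0, 10, 20), c(0, 0, 0))
  expect_warning(tf3 <- estimateFrameTransform(p3, sweep(p3, 2, c(2, 3), "+"),
                                               "affine"), "fell back")
  expect_equal(unname(tf3@params[1, ]), c(2, 3), tolerance = 1e-12)
})

test_that("affine inversion and composition behave analytically", {
  set.seed(59)
  p <- cbind(runif(8, 0, 60), runif(8, 0, 60))
  A <- matrix(c(0.98, 0.05, -0.04, 1.03), 2, 2)
  q <- t(A %*% t(p) + c(2, 5))
  tf <- estimateFrameTransform(p, q, "affine")
  inv <- invertTransform(tf)
  expect_lt(max(abs(applyTransform(inv, q) - p)), 1e-9)
  # composition associativity within numerical tolerance
  r <- applyTransform(tf, applyTransform(tf, p))
  r2 <- applyTransform(tf, applyTransform(tf, applyTransform(inv, q)))
  expect_lt(max(abs(r - r2)), 1e-9)
  expect_error(invertTransform(estimateFrameTransform(
    cbind(runif(8), runif(8)), cbind(runif(8), runif(8)), "polynomial-2")),
    class = "beas_noninvertible")
})

test_that("ROIs propagate forward by composition and refuse impossible backs", {
  idt <- estimateFrameTransform(cbind(1:4, 1:4), cbind(1:4, 1:4), "translation")
  roi <- list(roi_id = 1L, vertices = cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)))
  stat <- propagateROIs(list(roi), rep(list(idt), 9))
  expect_equal(stat[[1]]$vertices[[10]], roi$vertices, tolerance = 1e-12)
  # constant (1, 0) translation over 10 frames displaces by (10, 0)
  sh <- estimateFrameTransform(cbind(1:4, 1:4), cbind(2:5, 1:4), "translation")
  mv <- propagateROIs(list(roi), rep(list(sh), 10))
  expect_equal(mv[[1]]$vertices[[11]],
               sweep(roi$vertices, 2, c(10, 0), "+"), tolerance = 1e-9)
  # backward propagation from frame 3 through translations works
  roi3 <- list(roi_id = 2L, vertices = roi$vertices, frame = 3L)
  bk <- propagateROIs(list(roi3), rep(list(sh), 4))
  expect_equal(bk[[1]]$vertices[[1]],
               sweep(roi$vertices, 2, c(-2, 0), "+"), tolerance = 1e-9)
  expect_false(bk[[1]]$backwardRefused)
})

test_that("ROI propagation tracks a scene with known global affine motion", {
  cfg <- sceneConfig(nCells = 5, nFrames = 15, overlapFactor = 0,
                     imageSize = c(160L, 160L),
                     motion = list(type = "global_affine", rotation = 0.004,
                                   drift = c(0.8, 0.4), amplitude = 3),
                     transients = NULL, blur = NULL, seed = 61)
  sc <- generateScene(cfg)
  # landmarks: the true centroid trajectories
  tfs <- lapply(1:14, function(f) {
    a <- do.call(rbind, lapply(sc$truth@centers, function(m) m[f, ]))
    b <- do.call(rbind, lapply(sc$truth@centers, function(m) m[f + 1, ]))
    estimateFrameTransform(a, b, "affine", frames = c(f, f + 1))
  })
  roi <- list(roi_id = 1L, vertices = cbind(c(70, 80, 80, 70), c(70, 70, 80, 80)))
  tracked <- propagateROIs(list(roi), tfs)
  # ground truth: chain the generator's own per-frame transforms
  v <- roi$vertices
  for (f in 1:14) {
    tfTrue <- sc$truth@transforms[[f]]
    v <- t(tfTrue$M %*% t(v) + tfTrue$offset)
    err <- max(sqrt(rowSums((tracked[[1]]$vertices[[f + 1]] - v)^2)))
    expect_lt(err, 1)
  }
})

test_that("ROI signal extraction averages the rasterized interior", {
  stack <- array(0.7, dim = c(40, 40, 3))
  roi <- list(roi_id = 1L, vertices = cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)))
  idt <- estimateFrameTransform(cbind(1:3, 1:3), cbind(1:3, 1:3), "translation")
  tracked <- propagateROIs(list(roi), rep(list(idt), 2))
  sig <- extractROISignals(stack, tracked)
  expect_equal(sig$mean_intensity, rep(0.7, 3))
  expect_true(all(sig$n_pixels > 0))
  # an ROI fully outside the image is flagged
  far <- list(roi_id = 2L, vertices = cbind(c(100, 110, 110, 100), c(5, 5, 15, 15)))
  trackedFar <- propagateROIs(list(far), rep(list(idt), 2))
  sigFar <- extractROISignals(stack, trackedFar)
  expect_true(all(sigFar$status == "lost"))
  expect_true(all(is.na(sigFar$mean_intensity)))
})
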