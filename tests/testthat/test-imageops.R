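# Primitive operators against brute-force oracles and their declared
# contracts.

test_that("median despeckle removes speckle and matches the sorted-median oracle", {
  expect_equal(medianDespeckle(matrix(7, 12, 12)), matrix(7, 12, 12))

  img <- matrix(3, 11, 11)
  img[6, 6] <- 250
  out <- medianDespeckle(img)
  expect_equal(out[6, 6], 3)

  set.seed(11)
  for (i in 1:20) {
    r <- matrix(runif(81, 0, 100), 9, 9)
    expect_equal(medianDespeckle(r), o_median3x3(r))
  }
})

test_that("rolling-ball background is an idempotent lower envelope equal to the exhaustive opening", {
  # constant image: opening is the image, residual all zero
  expect_equal(rollingBallSubtract(matrix(42, 40, 40), 25),
               matrix(0, 40, 40))

  set.seed(21)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  for (r in c(5, 25)) {
    bg <- rollingBallBackground(img, r)
    expect_equal(bg, o_opening(img, r), tolerance = 1e-12)
    # lower envelope + residual bounded by input
    expect_true(all(bg <= img + 1e-12))
    res <- rollingBallSubtract(img, r)
    expect_true(all(res >= 0) && all(res <= img + 1e-12))
    # idempotence of the background estimate
    expect_equal(rollingBallBackground(bg, r), bg, tolerance = 1e-9)
  }
})

test_that("rolling ball removes a linear ramp but preserves a narrow punctum", {
  ny <- 64
  ramp <- matrix(rep(seq(0, 40, length.out = ny), each = ny), ny, ny)
  spot <- matrix(0, ny, ny)
  ys <- 29:35; xs <- 29:35
  for (y in ys) for (x in xs) {
    d2 <- (y - 32)^2 + (x - 32)^2
    if (d2 <= 9) spot[y, x] <- 100 * exp(-d2 / (2 * 1.5^2))
  }
  out <- rollingBallSubtract(ramp + spot, 25)
  # peak preserved within 10%
  expect_gt(out[32, 32], 0.9 * spot[32, 32])
  # ramp residual below 5% of its amplitude away from the punctum and
  # outside the border band (one ball radius), where the truncated
  # footprint makes the opening a weaker envelope -- exactly as the
  # exhaustive oracle does too
  far <- out[, c(1:20, 40:(64 - 26))]
  expect_lt(max(far), 0.05 * 40)
  expect_equal(out, pmax(ramp + spot - o_opening(ramp + spot, 25), 0),
               tolerance = 1e-12)
})

test_that("gaussian blur matches the closed-form kernel and a direct 2D convolution", {
  # delta impulse: discrete kernel vs normalised continuous kernel
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  out <- gaussianBlur(img, 1)
  cont <- function(dy, dx) exp(-(dy^2 + dx^2) / 2)
  norm <- sum(outer(-4:4, -4:4, cont))
  expect_equal(out[11, 11], cont(0, 0) / norm, tolerance = 0.01)
  expect_equal(out[11, 12], cont(0, 1) / norm, tolerance = 0.01)
  expect_equal(out[12, 12], cont(1, 1) / norm, tolerance = 0.01)

  expect_equal(gaussianBlur(matrix(5, 16, 16), 2), matrix(5, 16, 16))

  set.seed(31)
  r <- matrix(runif(24 * 18, 0, 10), 24, 18)
  expect_equal(gaussianBlur(r, 0.75), o_gauss2d(r, 0.75),
               tolerance = 1e-12)

  # total intensity conserved on interior-supported signals
  img2 <- matrix(0, 40, 40)
  img2[18:22, 18:22] <- runif(25, 0, 50)
  expect_equal(sum(gaussianBlur(img2, 1)), sum(img2),
               tolerance = 1e-3)
})

test_that("global threshold: fixed values, Otsu on a reference, strict > membership", {
  img <- matrix(c(10, 100)[1 + (runif(400) > 0.5)], 20, 20)
  m <- globalThreshold(img, value = 50)
  expect_identical(maskData(m)[, , 1], img > 50)
  expect_equal(provenance(m)$method, "fixed")

  # threshold at the maximum leaves an empty mask (strict >)
  m2 <- globalThreshold(img, value = max(img))
  expect_false(any(maskData(m2)))

  # Otsu equals the exhaustive between-class scan on bimodal samples
  set.seed(41)
  for (i in 1:10) {
    v <- c(rnorm(400, 20, 3), rnorm(200, 80, 6))
    expect_equal(otsuThreshold(v), o_otsu(v))
  }
  expect_error(globalThreshold(img), "reference")
})

test_that("mask arithmetic obeys the boolean identities", {
  set.seed(51)
  for (i in 1:20) {
    a <- BinaryMask(array(runif(4 * 6 * 3) > 0.5, c(4, 6, 3)))
    b <- BinaryMask(array(runif(4 * 6 * 3) > 0.5, c(4, 6, 3)))
    expect_false(any(maskData(maskSubtract(a, a))))
    empty <- BinaryMask(array(FALSE, c(4, 6, 3)))
    expect_identical(maskData(maskSubtract(a, empty)), maskData(a))
    # partition identity |a \ b| + |a & b| = |a|
    expect_equal(sum(maskData(maskSubtract(a, b))) +
                   sum(maskData(maskIntersect(a, b))),
                 sum(maskData(a)))
    # subtraction output disjoint from b
    expect_false(any(maskData(maskSubtract(a, b)) & maskData(b)))
    # union is commutative
    expect_identical(maskData(maskUnion(a, b)),
                     maskData(maskUnion(b, a)))
  }
  bad <- BinaryMask(array(FALSE, c(4, 6, 2)))
  expect_error(maskSubtract(bad, BinaryMask(array(FALSE, c(4, 6, 3)))),
               "shape")
})

test_that("3D labelling matches the flood-fill oracle and honours connectivity", {
  empty <- array(FALSE, c(8, 8, 4))
  expect_equal(nrow(labelObjects3D(empty)$objects), 0L)

  # two 2-voxel blobs touching only diagonally across a slice
  m <- array(FALSE, c(6, 6, 2))
  m[2, 2, 1] <- m[2, 3, 1] <- TRUE
  m[3, 4, 2] <- m[3, 5, 2] <- TRUE
  expect_equal(nrow(labelObjects3D(m, 26)$objects), 1L)
  expect_equal(nrow(labelObjects3D(m, 6)$objects), 2L)

  set.seed(61)
  for (i in 1:25) {
    msk <- array(runif(16^3) < runif(1, 0.1, 0.4), c(16, 16, 16))
    for (conn in c(6L, 26L)) {
      got <- labelObjects3D(msk, conn, minVoxels = 1L)
      want <- o_label3d(msk, conn)
      expect_identical(as.vector(got$labels), as.vector(want))
    }
  }

  # size filter and calibrated volume
  m2 <- array(FALSE, c(10, 10, 3))
  m2[2:3, 2:3, 1] <- TRUE           # 4 voxels
  m2[8, 8, 3] <- TRUE               # 1 voxel
  lab <- labelObjects3D(m2, 26, minVoxels = 2, voxelSize = c(0.5, 0.2, 0.2))
  expect_equal(nrow(lab$objects), 1L)
  expect_equal(lab$objects$volume_um3, 4 * 0.5 * 0.2 * 0.2)
  expect_error(labelObjects3D(m2, minVoxels = 5, maxVoxels = 2))
})

test_that("maxima detection follows prominence-by-flooding semantics", {
  # single Gaussian spot
  img <- outer(1:32, 1:32, function(y, x)
    10 * exp(-((y - 16)^2 + (x - 20)^2) / 8))
  pts <- findMaxima(img, 3)
  expect_equal(nrow(pts), 1L)
  expect_equal(c(pts$y, pts$x), c(16, 20))

  # two equal spots: valley deeper than tolerance -> 2, shallower -> 1
  two <- outer(1:40, 1:40, function(y, x)
    10 * exp(-((y - 20)^2 + (x - 15)^2) / 18) +
      10 * exp(-((y - 20)^2 + (x - 25)^2) / 18))
  peak <- max(two)
  valley <- min(two[20, 15:25])
  expect_equal(nrow(findMaxima(two, peak - valley - 0.5)), 2L)
  expect_equal(nrow(findMaxima(two, peak - valley + 0.5)), 1L)

  # plateau reports its centroid; an all-zero region reports nothing
  plat <- matrix(0, 10, 10)
  plat[4:5, 6:7] <- 2
  p <- findMaxima(plat, 0.5)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$y, p$x), c(4.5, 6.5))
  expect_equal(nrow(findMaxima(matrix(0, 5, 5), 1)), 0L)
  expect_error(findMaxima(plat, 1, region = matrix(FALSE, 10, 10)),
               "empty region")

  # random quantised images against the exhaustive oracle
  set.seed(71)
  for (i in 1:8) {
    r <- gaussianBlur(matrix(runif(32 * 32, 0, 10), 32, 32), 1.2)
    r <- round(r * 4) / 4
    for (tol in c(0.5, 1.5, 3)) {
      got <- findMaxima(r, tol)
      want <- o_find_maxima(r, tol)
      expect_equal(nrow(got), nrow(want))
      got <- got[order(-got$value, got$y, got$x), ]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                   tolerance = 1e-12)
    }
  }
})

test_that("projection, masked means and area fractions match loop oracles", {
  one <- array(runif(8 * 8), c(8, 8, 1))
  expect_equal(maxProject(one), one[, , 1])

  set.seed(81)
  vol <- array(runif(6 * 7 * 5, 0, 50), c(6, 7, 5))
  proj <- maxProject(vol)
  for (y in 1:6) for (x in 1:7)
    expect_equal(proj[y, x], max(vol[y, x, ]))

  msk <- array(runif(6 * 7 * 5) > 0.4, c(6, 7, 5))
  expect_equal(meanIntensity(vol, msk), mean(vol[msk]))
  expect_error(meanIntensity(vol, array(FALSE, dim(vol))), "empty")

  cimg <- array(3.5, c(5, 5, 2))
  allm <- array(TRUE, c(5, 5, 2))
  expect_equal(meanIntensity(cimg, allm), 3.5)
  expect_equal(areaFraction(matrix(TRUE, 5, 5)), 1)
  m2d <- matrix(runif(100) > 0.7, 10, 10)
  expect_equal(areaFraction(m2d), sum(m2d) / 100)
})

test_that("overlap coefficient: Cauchy-Schwarz bounds, scale invariance, oracle equality", {
  a <- array(runif(5 * 5 * 3, 1, 10), c(5, 5, 3))
  expect_equal(overlapCoefficient(a, a), 1)

  b <- array(0, dim(a)); b[1:2, , ] <- 7
  c2 <- array(0, dim(a)); c2[4:5, , ] <- 3
  expect_equal(overlapCoefficient(b, c2), 0)

  set.seed(91)
  for (i in 1:20) {
    p <- array(runif(60, 0, 5), c(4, 5, 3))
    q <- array(runif(60, 0, 5), c(4, 5, 3))
    r <- overlapCoefficient(p, q)
    expect_equal(r, o_overlap(p, q))
    expect_true(r >= 0 && r <= 1)
    expect_equal(overlapCoefficient(7 * p, q), r, tolerance = 1e-12)
    expect_equal(overlapCoefficient(q, p), r)
    mA <- array(runif(60) > 0.5, dim(p))
    mB <- array(runif(60) > 0.5, dim(p))
    expect_equal(overlapCoefficient(p, q, mA, mB),
                 o_overlap(p, q, as.vector(mA | mB)))
  }
  z <- array(0, dim(a))
  expect_error(overlapCoefficient(a, z), "zero")
})
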