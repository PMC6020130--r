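test_that("noiseless prolate tensor is recovered with the hand-computed FA", {
  evals <- c(1.5e-3, 0.5e-3, 0.5e-3)
  ph <- defaultBundlePhantom(evals = evals)
  tm <- fitTensor(ph$volume)
  b <- which(ph$wmMask, arr.ind = TRUE)[1, ]
  # FA = sqrt(3/2 * sum((l - mean)^2) / sum(l^2)) evaluated by hand
  lbar <- mean(evals)
  faHand <- sqrt(1.5 * sum((evals - lbar)^2) / sum(evals^2))
  expect_equal(faHand, 0.6030227, tolerance = 1e-7)
  expect_equal(faMap(tm)[b[1], b[2], b[3]], faHand, tolerance = 1e-10)
  expect_equal(adMap(tm)[b[1], b[2], b[3]], 1.5e-3, tolerance = 1e-12)
  expect_equal(rdMap(tm)[b[1], b[2], b[3]], 0.5e-3, tolerance = 1e-12)
  expect_equal(mdMap(tm)[b[1], b[2], b[3]], lbar, tolerance = 1e-12)
})

test_that("isotropic voxels fit to FA = 0 with AD = RD = MD", {
  ph <- makePhantom(phantomSpec(gridShape = c(4, 4, 2), bundles = list(),
                                background = 0.7e-3))
  tm <- fitTensor(ph$volume)
  expect_lt(max(faMap(tm)), 1e-10)
  expect_equal(max(abs(adMap(tm) - 0.7e-3)), 0, tolerance = 1e-15)
  expect_equal(max(abs(rdMap(tm) - 0.7e-3)), 0, tolerance = 1e-15)
})

test_that("the full tensor field is recovered to 1e-10 relative error noiselessly", {
  # oblique bundle: orientation not aligned with any axis
  ph <- makePhantom(phantomSpec(
    gridShape = c(16, 16, 8),
    bundles = list(straightBundle(c(3, 3, 6), c(13, 13, 10), radius = 2,
                                  label = 1))
  ))
  tm <- fitTensor(ph$volume)
  scaleRef <- max(abs(ph$truth@tensor))
  expect_lt(max(abs(tm@tensor - ph$truth@tensor)) / scaleRef, 1e-10)
  expect_lt(max(abs(tm@eigenvalues - ph$truth@eigenvalues)) /
              max(ph$truth@eigenvalues), 1e-10)
})

test_that("FA is invariant under rotation of the bundle orientation", {
  evals <- c(1.5e-3, 0.3e-3, 0.3e-3)
  phA <- makePhantom(phantomSpec(
    gridShape = c(16, 16, 8),
    bundles = list(straightBundle(c(3, 8, 8), c(13, 8, 8), 2, 1,
                                  evals = evals))
  ))
  phB <- makePhantom(phantomSpec(
    gridShape = c(16, 16, 8),
    bundles = list(straightBundle(c(3, 3, 6), c(13, 13, 10), 2, 1,
                                  evals = evals))
  ))
  faA <- faMap(fitTensor(phA$volume))[phA$wmMask]
  faB <- faMap(fitTensor(phB$volume))[phB$wmMask]
  expect_equal(unique(round(faA, 8)), unique(round(faB, 8)))
  expect_lt(max(abs(faA - faA[1])), 1e-8)
})

test_that("eigenvalue ordering and AD >= MD >= RD hold under noise", {
  ph <- defaultBundlePhantom(noiseSigma = 2, seed = 9)
  tm <- fitTensor(ph$volume)
  ev <- matrix(tm@eigenvalues, ncol = 3)
  expect_true(all(ev[, 1] >= ev[, 2] & ev[, 2] >= ev[, 3]))
  expect_true(all(adMap(tm) >= mdMap(tm) - 1e-15))
  expect_true(all(mdMap(tm) >= rdMap(tm) - 1e-15))
  expect_true(all(faMap(tm) >= 0 & faMap(tm) <= 1))
})

test_that("FA bias shrinks as SNR grows on a fixed phantom", {
  evals <- c(1.5e-3, 0.5e-3, 0.5e-3)
  faTrue <- 0.6030227
  biasAt <- function(sigma) {
    ph <- defaultBundlePhantom(noiseSigma = sigma, seed = 21,
                               evals = evals)
    tm <- fitTensor(ph$volume)
    abs(stats::median(faMap(tm)[ph$wmMask]) - faTrue)
  }
  expect_lt(biasAt(1), biasAt(8))
})

test_that("non-positive signals exclude a voxel from the fitted maps", {
  ph <- defaultBundlePhantom()
  vol <- ph$volume
  vol@signal[5, 5, 3, 4] <- 0
  tm <- fitTensor(vol)
  expect_false(tm@mask[5, 5, 3])
  expect_identical(faMap(tm)[5, 5, 3], 0)
  expect_true(all(tm@mask[-5, , ]))
})

test_that("a rank-deficient gradient scheme is rejected", {
  ph <- defaultBundlePhantom()
  vol <- ph$volume
  nvol <- length(vol@bvals)
  vol@bvecs[, 2:nvol] <- matrix(c(1, 0, 0), 3, nvol - 1)
  expect_error(fitTensor(vol), "rank-deficient")
})

test_that("motion QC applies the strict 1.5 mm limit with 50 mm arc conversion", {
  zero <- matrix(0, 10, 6)
  expect_identical(motionQC(zero)$decision, "retain")

  atLimit <- zero
  atLimit[5, 2] <- 1.5  # exactly at the limit: retained ("exceeded" is strict)
  expect_identical(motionQC(atLimit)$decision, "retain")

  over <- zero
  over[5, 1] <- 2.0
  res <- motionQC(over)
  expect_identical(res$decision, "exclude")
  expect_equal(res$maxTransMm, 2.0)

  rot <- zero
  rot[7, 5] <- 0.04  # 0.04 rad * 50 mm = 2.0 mm arc displacement
  res <- motionQC(rot)
  expect_identical(res$decision, "exclude")
  expect_equal(res$maxRotMm, 2.0)

  justUnder <- zero
  justUnder[3, 6] <- 0.029  # 1.45 mm at 50 mm radius
  expect_identical(motionQC(justUnder)$decision, "retain")

  expect_error(motionQC(matrix(0, 0, 6)), "empty")
})

test_that("TIV is the sum of tissue volumes and mask volumes match geometry", {
  expect_identical(computeTIV(600000, 500000), 1100000)
  expect_identical(computeTIV(0, 0), 0)
  expect_error(computeTIV(-1, 10), "nonnegative")

  # cylinder of radius 2 mm, length 18 mm: volume within one voxel
  # surface layer of the analytic value
  ph <- defaultBundlePhantom()
  vol <- maskVolume(ph$wmMask, c(1, 1, 2))
  analytic <- pi * 2^2 * 18
  surface <- 2 * pi * 2 * 18 * max(c(1, 1, 2))  # one voxel-layer bound
  expect_lt(abs(vol - analytic), surface)
})
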