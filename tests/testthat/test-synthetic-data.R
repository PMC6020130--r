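test_that("isotropic voxels give direction-independent signal at the closed-form value", {
  spec <- phantomSpec(gridShape = c(4, 4, 2), bundles = list(),
                      background = 0.7e-3, bValue = 1000, s0 = 100)
  ph <- makePhantom(spec)
  sig <- ph$volume@signal
  expect_equal(unname(sig[1, 1, 1, 1]), 100)
  dw <- sig[2, 3, 1, -1]
  expect_equal(dw, rep(100 * exp(-1000 * 0.7e-3), length(dw)),
               tolerance = 1e-12)
})

test_that("noiseless bundle signal matches an independently evaluated tensor law", {
  evals <- c(1.5e-3, 0.5e-3, 0.5e-3)
  ph <- defaultBundlePhantom(evals = evals)
  vol <- ph$volume
  # bundle axis is +x, transverse eigenvalues equal, so for gradient g
  # the decay exponent is l1*gx^2 + l2*(gy^2 + gz^2)
  inBundle <- which(ph$wmMask, arr.ind = TRUE)[1, ]
  g <- vol@bvecs
  expected <- 100 * exp(-1000 * (evals[1] * g[1, ]^2 +
                                   evals[2] * (g[2, ]^2 + g[3, ]^2)))
  expected[vol@bvals == 0] <- 100
  got <- vol@signal[inBundle[1], inBundle[2], inBundle[3], ]
  expect_equal(got, expected, tolerance = 1e-13)
})

test_that("bundle end caps become atlas regions; two bundles give four labels", {
  ph <- makePhantom(phantomSpec(
    gridShape = c(24, 12, 6),
    bundles = list(
      straightBundle(c(3, 3, 6), c(21, 3, 6), radius = 1.4, label = 1),
      straightBundle(c(3, 9, 6), c(21, 9, 6), radius = 1.4, label = 2)
    )
  ))
  labs <- sort(unique(as.integer(labelVolume(ph$atlas))))
  expect_identical(labs, c(0L, 1L, 2L, 3L, 4L))
  expect_identical(nRegions(ph$atlas), 4L)
  expect_identical(nrow(labelTable(ph$atlas)), 4L)
})

test_that("bundles outside the grid are rejected with a message", {
  expect_error(
    makePhantom(phantomSpec(
      gridShape = c(10, 10, 4),
      bundles = list(straightBundle(c(2, 5, 4), c(30, 5, 4), 2, 1))
    )),
    "outside"
  )
})

test_that("phantom generation is deterministic under a fixed seed", {
  mk <- function() makePhantom(phantomSpec(
    gridShape = c(8, 8, 4),
    bundles = list(straightBundle(c(2, 4, 4), c(6, 4, 4), 1.5, 1)),
    noiseSigma = 2, seed = 42
  ))
  expect_identical(mk()$volume@signal, mk()$volume@signal)
})

test_that("eigenvalue ordering in phantom specs is enforced", {
  expect_error(phantomSpec(
    gridShape = c(8, 8, 4),
    bundles = list(straightBundle(c(2, 4, 4), c(6, 4, 4), 1.5, 1,
                                  evals = c(0.5e-3, 1.5e-3, 0.5e-3)))
  ))
})

test_that("motion traces scale with amplitude and are zero at amplitude 0", {
  z <- makeMotionTrace(30, amplitude = 0)
  expect_true(all(z == 0))
  tr <- makeMotionTrace(30, amplitude = 0.5, seed = 3)
  expect_identical(dim(tr), c(30L, 6L))
  expect_true(all(tr[1, ] == 0))
  expect_identical(tr, makeMotionTrace(30, amplitude = 0.5, seed = 3))
})

test_that("cohort matrices are symmetric nonnegative integers with zero diagonal", {
  cc <- makeCohort(cohortSpec(nPatients = 6, nControls = 6,
                              groupEffect = list(),
                              clinicalEffects = list(), seed = 11))
  expect_length(cc$connectomes, 12L)
  for (cm in cc$connectomes[c(1, 7)]) {
    w <- counts(cm)
    expect_identical(dim(w), c(24L, 24L))
    expect_equal(w, t(w))
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0))
    expect_equal(w, round(w))
    ad <- meanAD(cm)
    expect_true(all((ad > 0) == (w > 0)))
  }
  expect_true(all(is.na(cc$cohort$puts[cc$cohort$group == "CS"])))
  expect_true(all(is.finite(cc$cohort$puts[cc$cohort$group == "TS"])))
})

test_that("cohort generation is reproducible and hub nodes carry top strength", {
  cc1 <- makeCohort(cohortSpec(seed = 5))
  cc2 <- makeCohort(cohortSpec(seed = 5))
  expect_identical(counts(cc1$connectomes[[3]]), counts(cc2$connectomes[[3]]))
  expect_identical(cc1$cohort, cc2$cohort)
  # use a control subject: free of planted-effect edge surgery
  strength <- rowSums(counts(cc1$connectomes[["CS01"]]))
  expect_setequal(order(strength, decreasing = TRUE)[1:2], c(5L, 14L))
})

test_that("planting the same node and metric twice is rejected", {
  expect_error(cohortSpec(
    groupEffect = list(),
    clinicalEffects = list(
      list(node = 21, metric = "local_efficiency", score = "puts",
           effect = 0.6),
      list(node = 21, metric = "local_efficiency", score = "ygtss",
           effect = 0.4)
    )
  ), "twice")
})

test_that("planted clinical associations come out with the right sign", {
  # Monte-Carlo sign recovery: positive local-efficiency/PUTS effects
  # at two insula nodes must yield positive covariate-adjusted slopes
  # in nearly all replicates
  signs <- vapply(1:20, function(sd) {
    cc <- makeCohort(cohortSpec(seed = sd, groupEffect = list()))
    pat <- cc$cohort[cc$cohort$group == "TS", ]
    vapply(c(21, 24), function(nd) {
      le <- vapply(cc$connectomes[pat$subject], function(x) {
        localEfficiency(proportionalThreshold(counts(x), 0.25))[nd]
      }, numeric(1))
      X <- cbind(1, le, scale(pat$age), scale(pat$iq), scale(pat$tiv))
      unname(stats::coef(stats::lm.fit(X, pat$puts))[2])
    }, numeric(1))
  }, numeric(2))
  expect_gte(mean(signs > 0), 0.9)
})
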