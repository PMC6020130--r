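# shared small cohort-like design for the permutation tests
fakeCohort <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    subject = sprintf("S%02d", 1:n),
    group = rep(c("TS", "CS"), length.out = n),
    age = stats::runif(n, 9, 21),
    iq = stats::rnorm(n, 110, 12),
    tiv = stats::rnorm(n, 1.4e6, 1e5),
    stringsAsFactors = FALSE
  )
}

test_that("BH step-up matches the hand-worked examples", {
  # p = (.01, .02, .04, .05): largest k with p(k) <= k * .05/4 is 4
  res <- fdrCorrect(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$adjusted[4], 0.05)

  expect_false(any(fdrCorrect(rep(1, 10))$reject))
  expect_true(fdrCorrect(0.04)$reject)

  set.seed(8)
  p <- stats::runif(50)
  res <- fdrCorrect(p)
  expect_true(all(diff(res$adjusted[order(p)]) >= -1e-12))
  expect_identical(res$reject, res$adjusted <= 0.05)
  # BY is never less conservative than BH
  expect_true(all(fdrCorrect(p, method = "BY")$adjusted >=
                    res$adjusted - 1e-12))
  expect_length(fdrCorrect(numeric())$adjusted, 0L)
})

test_that("a constant metric yields p = 1 with a warning", {
  co <- fakeCohort()
  expect_warning(res <- permutationGroupTest(rep(2, 30), co), "constant")
  expect_identical(res$p, 1)
})

test_that("permutation p-values ignore subject order and covariate scaling", {
  co <- fakeCohort(seed = 2)
  y <- stats::rnorm(30) + 0.8 * (co$group == "TS")
  base <- permutationGroupTest(y, co, nPerm = 500, seed = 9)

  shuffle <- sample(30)
  perm <- permutationGroupTest(y[shuffle], co[shuffle, ],
                               nPerm = 500, seed = 9)
  expect_identical(base$p, perm$p)
  expect_equal(base$statistic, perm$statistic)

  co2 <- co
  co2$age <- co2$age * 12 + 7      # months, offset
  co2$tiv <- co2$tiv / 1000        # cm^3
  resc <- permutationGroupTest(y, co2, nPerm = 500, seed = 9)
  expect_equal(base$statistic, resc$statistic, tolerance = 1e-10)
  expect_identical(base$p, resc$p)
})

test_that("permutation p never returns zero and doubling nPerm moves p only by MC error", {
  co <- fakeCohort(seed = 3)
  y <- stats::rnorm(30) + 3 * (co$group == "TS")  # huge effect
  res <- permutationGroupTest(y, co, nPerm = 200, seed = 1)
  expect_gte(res$p, 1 / 201)

  y2 <- stats::rnorm(30) + 0.5 * (co$group == "TS")
  p1 <- permutationGroupTest(y2, co, nPerm = 1000, seed = 4)$p
  p2 <- permutationGroupTest(y2, co, nPerm = 2000, seed = 5)$p
  mcSE <- sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(p1 - p2), 5 * mcSE + 2e-3)
})

test_that("the group test holds its size on null data", {
  co <- fakeCohort(n = 40, seed = 6)
  set.seed(60)
  hits <- sum(vapply(1:60, function(i) {
    permutationGroupTest(stats::rnorm(40), co, nPerm = 199,
                         seed = NULL)$p < 0.05
  }, logical(1)))
  # binomial(60, .05): mean 3, sd 1.7
  expect_lte(hits, 9)
})

test_that("singular designs are rejected", {
  co <- fakeCohort()
  co$tiv <- co$age  # collinear covariates
  expect_error(permutationGroupTest(stats::rnorm(30), co), "singular")
})

test_that("the association scan covers the full grid and only uses patients", {
  cc <- makeCohort(cohortSpec(nPatients = 12, nControls = 12,
                              groupEffect = list(), seed = 15))
  m <- computeMetrics(cc$connectomes, thresholds = c(0.2, 0.3),
                      nNull = 20, seed = 1)
  scan <- clinicalAssociationScan(m, cc$cohort, score = "puts")
  # 2 thresholds x 24 nodes x 9 metrics
  expect_identical(nrow(scan), 2L * 24L * 9L)
  expect_setequal(unique(scan$metric),
                  c("degree", "betweenness", "path_length", "clustering",
                    "local_efficiency", "density", "global_efficiency",
                    "assortativity", "small_worldness"))

  # corrupting control rows must not change the scan
  m2 <- m
  ctl <- cc$cohort$subject[cc$cohort$group == "CS"]
  m2$nodal$value[m2$nodal$subject %in% ctl] <- 999
  scan2 <- clinicalAssociationScan(m2, cc$cohort, score = "puts")
  expect_identical(scan$t, scan2$t)

  # density is constant across patients by construction: NA cells
  expect_true(all(is.na(scan$t[scan$metric == "density"])))

  tiny <- cc$cohort[c(1:4, 13:16), ]
  expect_error(clinicalAssociationScan(m, tiny, score = "puts"),
               "fewer patients")
})

test_that("a strongly planted association is localized by the scan's max |t|", {
  # synthetic metric tables: one node of one metric tracks the score
  set.seed(23)
  nPat <- 26
  subj <- sprintf("TS%02d", 1:nPat)
  cohort <- data.frame(
    subject = subj, group = "TS",
    age = stats::runif(nPat, 9, 21), iq = stats::rnorm(nPat, 110, 12),
    tiv = stats::rnorm(nPat, 1.4e6, 1e5),
    puts = NA_real_, stringsAsFactors = FALSE
  )
  hits <- vapply(1:20, function(rep) {
    score <- stats::rnorm(nPat, 20, 5)
    thresholds <- seq(0.2, 0.25, by = 0.01)
    nodal <- expand.grid(subject = subj, threshold = thresholds,
                         node = 1:24, metric = c("degree", "clustering"),
                         stringsAsFactors = FALSE)
    nodal$value <- stats::rnorm(nrow(nodal))
    planted <- nodal$node == 7 & nodal$metric == "clustering"
    nodal$value[planted] <- nodal$value[planted] +
      2 * scale(score)[match(nodal$subject[planted], subj)]
    co <- cohort
    co$puts <- score
    scan <- clinicalAssociationScan(list(nodal = nodal,
                                         global = nodal[0, c(1, 2, 4, 5)]),
                                    co, score = "puts")
    best <- scan[which.max(abs(scan$t)), ]
    best$node == 7 && best$metric == "clustering"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("group comparison corrects per metric and handles undefined cells", {
  cc <- makeCohort(cohortSpec(nPatients = 8, nControls = 8,
                              groupEffect = list(),
                              clinicalEffects = list(), seed = 41))
  m <- computeMetrics(cc$connectomes, thresholds = c(0.2, 0.3), nNull = 0)
  res <- groupComparison(m, cc$cohort, nPerm = 99, seed = 2)
  nodalRows <- res[!is.na(res$node), ]
  expect_identical(nrow(nodalRows), 5L * 24L * 2L)
  # density never differs across subjects under proportional thresholding
  expect_true(all(res$p[res$metric == "density"] == 1))
  for (mn in unique(res$metric)) {
    sel <- res$metric == mn & !is.na(res$p)
    expect_identical(res$p_fdr[sel],
                     stats::p.adjust(res$p[sel], method = "BH"))
  }
})
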