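test_that("proportional thresholding keeps exactly the strongest k edges", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(5, 1, 3, 6, 2, 4)
  w <- w + t(w)
  adj <- proportionalThreshold(w, 0.5)  # k = round(0.5 * 6) = 3
  expect_identical(sum(adj) / 2, 3)
  kept <- which(upper.tri(adj) & adj > 0)
  expect_setequal(w[kept], c(4, 5, 6))
  expect_equal(adj, t(adj))
  expect_identical(attr(adj, "level"), 0.5)

  full <- proportionalThreshold(w, 1.0)
  expect_identical(networkDensity(full), 1)

  sparse <- matrix(0, 4, 4)
  sparse[1, 2] <- sparse[2, 1] <- 1
  expect_warning(out <- proportionalThreshold(sparse, 1.0), "nonzero")
  expect_identical(sum(out) / 2, 1)
})

test_that("the threshold grid holds 26 levels and ties break lexicographically", {
  expect_length(thresholdGrid(), 26L)
  # all-equal weights: the retained edges are the lexicographically first k
  w <- matrix(1, 5, 5); diag(w) <- 0
  adj <- proportionalThreshold(w, 0.3)  # k = round(3) = 3
  kept <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  expect_equal(unname(kept), cbind(c(1, 1, 1), c(2, 3, 4)),
               ignore_attr = TRUE)
})

test_that("textbook graphs give the textbook metric values", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(betweennessCentrality(path3), c(0, 1, 0))
  expect_equal(globalEfficiency(path3), (1 + 1 + 0.5) / 3,
               tolerance = 1e-12)
  expect_equal(as.numeric(nodalPathLength(path3)), c(1.5, 1, 1.5))

  star4 <- matrix(0, 4, 4)
  star4[1, 2:4] <- star4[2:4, 1] <- 1
  expect_equal(nodeDegree(star4), c(3, 1, 1, 1))
  expect_identical(networkDensity(star4), 0.5)
  expect_equal(betweennessCentrality(star4), c(3, 0, 0, 0))
  expect_equal(clusteringCoefficient(star4), rep(0, 4))

  k24 <- matrix(1, 24, 24); diag(k24) <- 0
  expect_true(all(nodeDegree(k24) == 23))
  expect_identical(networkDensity(k24), 1)
  expect_equal(characteristicPathLength(k24), 1)
  expect_equal(globalEfficiency(k24), 1)
  expect_equal(localEfficiency(k24), rep(1, 24))
  expect_equal(clusteringCoefficient(k24), rep(1, 24))
  expect_equal(betweennessCentrality(k24), rep(0, 24))

  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clusteringCoefficient(tri), rep(1, 3))

  # isolated node: zero local efficiency, no finite distances
  iso <- matrix(0, 4, 4)
  iso[1, 2] <- iso[2, 1] <- iso[2, 3] <- iso[3, 2] <- 1
  expect_identical(localEfficiency(iso)[4], 0)
  expect_true(is.nan(as.numeric(nodalPathLength(iso))[4]))
})

test_that("assortativity flags regular graphs as undefined", {
  ring <- smallWorldNetwork(10, nei = 1, pRewire = 0, seed = 1)
  expect_warning(r <- assortativityCoefficient(ring), "undefined")
  expect_true(is.nan(r))
})

test_that("every metric matches the exhaustive brute-force oracle on small graphs", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    adj <- randomGraph(n, stats::runif(1, 0.2, 0.55))
    expect_equal(nodeDegree(adj), rowSums(adj))
    expect_equal(betweennessCentrality(adj), oracleBetweenness(adj),
                 tolerance = 1e-12)
    expect_equal(as.numeric(nodalPathLength(adj)),
                 oracleNodalPathLength(adj))
    expect_equal(characteristicPathLength(adj), oracleCharPathLength(adj))
    expect_equal(globalEfficiency(adj), oracleGlobalEfficiency(adj),
                 tolerance = 1e-12)
    expect_equal(localEfficiency(adj), oracleLocalEfficiency(adj),
                 tolerance = 1e-12)
    expect_equal(clusteringCoefficient(adj), oracleClustering(adj))
    ra <- suppressWarnings(assortativityCoefficient(adj))
    ro <- oracleAssortativity(adj)
    if (is.na(ro)) expect_true(is.nan(ra)) else expect_equal(ra, ro)
  }
})

test_that("metrics are equivariant under node relabelling", {
  set.seed(77)
  adj <- randomGraph(12, 0.3)
  perm <- sample(12)
  padj <- adj[perm, perm]
  expect_equal(nodeDegree(padj), nodeDegree(adj)[perm])
  expect_equal(betweennessCentrality(padj),
               betweennessCentrality(adj)[perm])
  expect_equal(localEfficiency(padj), localEfficiency(adj)[perm])
  expect_equal(clusteringCoefficient(padj),
               clusteringCoefficient(adj)[perm])
  expect_equal(networkDensity(padj), networkDensity(adj))
  expect_equal(globalEfficiency(padj), globalEfficiency(adj))
  expect_equal(characteristicPathLength(padj),
               characteristicPathLength(adj))
})

test_that("null networks preserve degree sequence and edge count exactly", {
  net <- smallWorldNetwork(24, nei = 3, pRewire = 0.15, seed = 2)
  nulls <- generateNulls(net, n = 100, seed = 3)
  expect_length(nulls, 100L)
  changed <- FALSE
  for (nl in nulls) {
    expect_identical(rowSums(nl), rowSums(net))
    expect_identical(sum(nl), sum(net))
    expect_true(all(diag(nl) == 0))
    if (!identical(nl, net)) changed <- TRUE
  }
  expect_true(changed)  # the ensemble actually rewires
})

test_that("a star admits no degree-preserving swap and falls back to copies", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  expect_warning(nulls <- generateNulls(star, n = 5, seed = 1), "swap")
  expect_identical(nulls[[3]], star)
})

test_that("small-worldness normalizes to exactly 1 against itself and exceeds 1 on a lattice", {
  net <- smallWorldNetwork(24, nei = 3, pRewire = 0.1, seed = 4)
  self <- smallWorldness(net, replicate(20, net, simplify = FALSE))
  expect_equal(unname(self), c(1, 1, 1))

  nulls <- generateNulls(net, n = 200, seed = 5)
  meanNullClust <- mean(vapply(nulls, function(x) {
    mean(clusteringCoefficient(x))
  }, numeric(1)))
  expect_lt(meanNullClust, mean(clusteringCoefficient(net)))
  sw <- smallWorldness(net, nulls)
  expect_gt(sw["sigma"], 1)

  # a degree-matched random graph is its own null: sigma near 1
  set.seed(6)
  rnd <- randomGraph(24, 0.25)
  swRnd <- smallWorldness(rnd, generateNulls(rnd, n = 200, seed = 7))
  expect_lt(abs(swRnd["sigma"] - 1), 0.15)
})

test_that("the C++ null statistics agree with the R metric definitions", {
  set.seed(11)
  for (rep in 1:20) {
    adj <- randomGraph(sample(5:12, 1), stats::runif(1, 0.2, 0.7))
    e <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    storage.mode(e) <- "integer"
    if (nrow(e) == 0) next
    st <- dtiConnectome:::.cpp_graph_stats(e, nrow(adj))
    expect_equal(unname(st["clustering"]),
                 mean(clusteringCoefficient(adj)), tolerance = 1e-12)
    cpl <- characteristicPathLength(adj)
    if (is.nan(cpl)) {
      expect_true(is.na(st["path_length"]))
    } else {
      expect_equal(unname(st["path_length"]), cpl, tolerance = 1e-12)
    }
  }
})

test_that("hubs require z >= 2 on both degree and betweenness", {
  deg <- c(rep(10, 23), 30)
  btw <- c(rep(40, 23), 120)
  expect_identical(detectHubs(deg, btw), 24L)
  # high degree alone is not enough
  expect_identical(detectHubs(deg, rep(c(35, 45), 12)), integer(0))
  expect_warning(out <- detectHubs(rep(5, 24), rep(5, 24)), "variance")
  expect_identical(out, integer(0))
})

test_that("density is identical across subjects at each threshold level", {
  cc <- makeCohort(cohortSpec(nPatients = 4, nControls = 4,
                              groupEffect = list(),
                              clinicalEffects = list(), seed = 31))
  m <- computeMetrics(cc$connectomes, thresholds = c(0.15, 0.25, 0.40),
                      nNull = 0)
  dens <- m$global[m$global$metric == "density", ]
  for (thr in unique(dens$threshold)) {
    expect_length(unique(dens$value[dens$threshold == thr]), 1L)
  }
  # 5 nodal metrics x 24 nodes x 3 thresholds x 8 subjects
  expect_identical(nrow(m$nodal), 5L * 24L * 3L * 8L)
})
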