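# In-code fixtures shared across test files.

# build a TensorMaps object directly from a voxelwise direction
# function (signature function(i, j, k) -> unit 3-vector), with
# constant eigenvalues; used to craft direction fields (corridors,
# bends, arcs) without going through the phantom generator
makeTensorField <- function(gridShape, dirAt,
                            evals = c(1.5e-3, 0.3e-3, 0.3e-3),
                            voxelSize = c(1, 1, 1)) {
  gs <- as.integer(gridShape)
  nvox <- prod(gs)
  ev <- matrix(evals, nvox, 3, byrow = TRUE)
  v1 <- matrix(0, nvox, 3)
  d6 <- matrix(0, nvox, 6)
  idx <- arrayInd(seq_len(nvox), gs)
  frameFrom <- get(".frameFrom", asNamespace("dtiConnectome"))
  for (r in seq_len(nvox)) {
    u <- dirAt(idx[r, 1], idx[r, 2], idx[r, 3])
    u <- u / sqrt(sum(u^2))
    R <- frameFrom(u)
    D <- R %*% diag(evals) %*% t(R)
    d6[r, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    v1[r, ] <- u
  }
  md <- mean(evals)
  fa <- sqrt(1.5 * sum((evals - md)^2) / sum(evals^2))
  arr3 <- function(x) array(x, gs)
  new("TensorMaps",
    eigenvalues = array(ev, c(gs, 3L)), v1 = array(v1, c(gs, 3L)),
    tensor = array(d6, c(gs, 6L)),
    fa = arr3(rep(fa, nvox)), md = arr3(rep(md, nvox)),
    ad = arr3(rep(evals[1], nvox)),
    rd = arr3(rep(mean(evals[2:3]), nvox)),
    mask = arr3(rep(TRUE, nvox)), clamped = arr3(rep(FALSE, nvox)),
    voxelSize = voxelSize
  )
}

# straight single-bundle phantom reused by several files
defaultBundlePhantom <- function(noiseSigma = 0, seed = 1L,
                                 evals = c(1.5e-3, 0.5e-3, 0.5e-3)) {
  makePhantom(phantomSpec(
    gridShape = c(24, 10, 6),
    bundles = list(straightBundle(c(3, 5, 6), c(21, 5, 6), radius = 2,
                                  label = 1, evals = evals)),
    noiseSigma = noiseSigma, seed = seed
  ))
}

# small fast cohort for pipeline-level tests
smallRunConfig <- function(dir, seed = 1L) {
  cfg <- defaultRunConfig()
  cfg$outputDir <- dir
  cfg$nPatients <- 10L
  cfg$nControls <- 10L
  cfg$thresholdMin <- 0.20
  cfg$thresholdMax <- 0.25
  cfg$nNull <- 40L
  cfg$nPerm <- 99L
  cfg$seed <- as.integer(seed)
  cfg
}
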