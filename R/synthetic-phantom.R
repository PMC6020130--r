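#' Construct a phantom specification
#'
#' Convenience constructor for [PhantomSpec-class] with study-style
#' defaults: 1 x 1 x 2 mm voxels, b = 1000 s/mm^2, 32 gradient
#' directions and a 0.7e-3 mm^2/s isotropic background (typical
#' grey-matter diffusivity).
#'
#' @param gridShape integer length-3 grid size in voxels.
#' @param bundles list of bundle descriptions; see [PhantomSpec-class].
#' @param voxelSize voxel dimensions in mm.
#' @param background isotropic background diffusivity in mm^2/s.
#' @param bValue diffusion weighting in s/mm^2.
#' @param nDirections number of diffusion-encoding directions.
#' @param s0 baseline signal.
#' @param noiseSigma Rician noise scale (0 = noiseless).
#' @param seed RNG seed used when noise is added.
#' @return a validated [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(
#'   gridShape = c(20, 8, 6),
#'   bundles = list(straightBundle(
#'     start = c(2, 4, 6), end = c(18, 4, 6), radius = 2, label = 1
#'   ))
#' )
#' @export
phantomSpec <- function(gridShape, bundles = list(),
                        voxelSize = c(1, 1, 2),
                        background = 0.7e-3, bValue = 1000,
                        nDirections = 32L, s0 = 100,
                        noiseSigma = 0, seed = 1L) {
  new("PhantomSpec",
    gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
    bundles = bundles, background = background, bValue = bValue,
    nDirections = as.integer(nDirections), s0 = s0,
    noiseSigma = noiseSigma, seed = as.integer(seed)
  )
}

#' Describe a straight cylindrical bundle
#'
#' @param start,end bundle axis endpoints in mm.
#' @param radius cylinder radius in mm.
#' @param evals tensor eigenvalues along/across the axis (mm^2/s,
#'   descending); the default is a strongly anisotropic white-matter-like
#'   tensor.
#' @param label integer bundle label; end caps become atlas regions
#'   2*label - 1 and 2*label.
#' @param capLength length (mm) of each end cap labelled as an ROI.
#' @return a bundle description list for [phantomSpec()].
#' @export
straightBundle <- function(start, end, radius, label,
                           evals = c(1.5e-3, 0.3e-3, 0.3e-3),
                           capLength = 3) {
  list(start = as.numeric(start), end = as.numeric(end),
       radius = radius, evals = as.numeric(evals),
       label = as.integer(label), capLength = capLength)
}

#' Deterministic gradient scheme on the unit sphere
#'
#' Spherical Fibonacci point set: a well-spread, reproducible set of
#' unit direction vectors. Adequately conditions the 6-parameter tensor
#' fit for any n >= 6.
#'
#' @param n number of directions.
#' @return 3 x n matrix of unit column vectors.
#' @export
gradientScheme <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

# voxel-centre coordinates (mm) for a grid; centre of voxel i is
# (i - 0.5) * voxelSize
.voxelCentres <- function(gridShape, voxelSize) {
  g <- expand.grid(
    x = (seq_len(gridShape[1]) - 0.5) * voxelSize[1],
    y = (seq_len(gridShape[2]) - 0.5) * voxelSize[2],
    z = (seq_len(gridShape[3]) - 0.5) * voxelSize[3]
  )
  as.matrix(g)
}

# orthonormal frame with first axis u
.frameFrom <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  cbind(u, v, w)
}

# scalar maps from an (nvox x 3) eigenvalue matrix (sorted descending)
.eigenScalars <- function(ev) {
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  list(fa = fa, md = md, ad = ev[, 1], rd = (ev[, 2] + ev[, 3]) / 2)
}

#' Generate a synthetic diffusion phantom
#'
#' Builds the four objects the downstream pipeline consumes from a
#' [PhantomSpec-class]: a noiseless or Rician-noised 4D
#' diffusion-weighted volume following the monoexponential tensor
#' signal law S(g) = S0 exp(-b g' D g), the ground-truth tensor maps
#' actually used at every voxel, the white-matter mask (bundle
#' voxels), and an ROI atlas labelling each bundle's two end caps.
#'
#' The first volume is the unweighted (b = 0) baseline; the remaining
#' \code{nDirections} volumes use a spherical-Fibonacci gradient
#' scheme. Bundles must lie fully inside the grid.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{volume} ([DiffusionVolume-class]),
#'   \code{truth} ([TensorMaps-class]), \code{wmMask} (logical 3D
#'   array) and \code{atlas} ([ROIAtlas-class]).
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  vs <- spec@voxelSize
  extent <- gs * vs
  for (b in spec@bundles) {
    pts <- rbind(b$start, b$end)
    if (any(pts < b$radius) ||
        any(sweep(pts, 2, extent - b$radius) > 0)) {
      stop("bundle ", b$label, " (including its radius) falls outside ",
           "the grid extent ", paste(round(extent, 1), collapse = " x "),
           " mm")
    }
  }

  centres <- .voxelCentres(gs, vs)
  nvox <- nrow(centres)

  # per-voxel tensor, stored as the 6 unique elements
  d6 <- matrix(0, nvox, 6)  # Dxx Dyy Dzz Dxy Dxz Dyz
  d6[, 1:3] <- spec@background
  ev <- matrix(spec@background, nvox, 3)
  v1 <- matrix(rep(c(1, 0, 0), each = nvox), nvox, 3)
  labels <- integer(nvox)
  wm <- logical(nvox)

  for (b in spec@bundles) {
    u <- b$end - b$start
    len <- sqrt(sum(u^2))
    u <- u / len
    rel <- sweep(centres, 2, b$start)
    t <- as.vector(rel %*% u)
    perp2 <- rowSums(rel^2) - t^2
    inside <- t >= 0 & t <= len & perp2 <= b$radius^2
    if (!any(inside)) next
    R <- .frameFrom(u)
    D <- R %*% diag(b$evals) %*% t(R)
    d6[inside, ] <- matrix(
      c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
      sum(inside), 6, byrow = TRUE
    )
    ev[inside, ] <- matrix(b$evals, sum(inside), 3, byrow = TRUE)
    v1[inside, ] <- matrix(u, sum(inside), 3, byrow = TRUE)
    wm[inside] <- TRUE
    cap <- b$capLength
    labels[inside & t <= cap] <- 2L * b$label - 1L
    labels[inside & t >= len - cap] <- 2L * b$label
  }

  # signal: one b0 volume plus the gradient scheme
  dirs <- gradientScheme(spec@nDirections)
  bvals <- c(0, rep(spec@bValue, spec@nDirections))
  bvecs <- cbind(c(0, 0, 0), dirs)
  nvol <- length(bvals)
  sig <- matrix(spec@s0, nvox, nvol)
  for (j in seq_len(spec@nDirections)) {
    g <- dirs[, j]
    q <- d6[, 1] * g[1]^2 + d6[, 2] * g[2]^2 + d6[, 3] * g[3]^2 +
      2 * (d6[, 4] * g[1] * g[2] + d6[, 5] * g[1] * g[3] +
             d6[, 6] * g[2] * g[3])
    sig[, j + 1] <- spec@s0 * exp(-spec@bValue * q)
  }
  if (spec@noiseSigma > 0) {
    set.seed(spec@seed)
    n1 <- matrix(stats::rnorm(nvox * nvol, 0, spec@noiseSigma), nvox, nvol)
    n2 <- matrix(stats::rnorm(nvox * nvol, 0, spec@noiseSigma), nvox, nvol)
    sig <- sqrt((sig + n1)^2 + n2^2)
  }

  sc <- .eigenScalars(ev)
  arr3 <- function(x) array(x, dim = gs)
  arr4 <- function(x) array(x, dim = c(gs, ncol(x)))

  volume <- new("DiffusionVolume",
    signal = arr4(sig), bvals = bvals, bvecs = bvecs,
    voxelSize = vs, brainMask = arr3(rep(TRUE, nvox))
  )
  truth <- new("TensorMaps",
    eigenvalues = arr4(ev), v1 = arr4(v1), tensor = arr4(d6),
    fa = arr3(sc$fa), md = arr3(sc$md), ad = arr3(sc$ad), rd = arr3(sc$rd),
    mask = arr3(rep(TRUE, nvox)), clamped = arr3(rep(FALSE, nvox)),
    voxelSize = vs
  )
  nlab <- max(labels, 0L)
  lt <- if (nlab > 0) {
    bl <- (seq_len(nlab) + 1L) %/% 2L
    data.frame(
      label = seq_len(nlab),
      name = paste0("bundle", bl, c("_start", "_end")[2L - seq_len(nlab) %% 2L]),
      hemisphere = NA_character_,
      system = "phantom",
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(label = integer(), name = character(),
               hemisphere = character(), system = character())
  }
  atlas <- new("ROIAtlas",
    labels = arr3(labels), labelTable = lt, voxelSize = vs
  )
  list(volume = volume, truth = truth, wmMask = arr3(wm), atlas = atlas)
}

#' Simulate a head-motion parameter trace
#'
#' Generates a per-volume realignment trace with three translations
#' (mm) and three rotations (radians) as a scaled random walk; the
#' first volume is the reference and is all zero. \code{amplitude}
#' sets the typical end-of-scan translation in mm; rotations are
#' scaled so that their arc displacement at a 50 mm radius is
#' comparable. \code{amplitude = 0} yields an all-zero trace.
#'
#' @param nVolumes number of volumes (rows).
#' @param amplitude typical cumulative displacement in mm.
#' @param seed RNG seed.
#' @return numeric matrix with columns trans_x, trans_y, trans_z (mm)
#'   and rot_x, rot_y, rot_z (radians).
#' @export
makeMotionTrace <- function(nVolumes, amplitude = 0.3, seed = 1L) {
  stopifnot(nVolumes >= 1, amplitude >= 0)
  trace <- matrix(0, nVolumes, 6)
  colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
  if (amplitude > 0 && nVolumes > 1) {
    set.seed(as.integer(seed))
    step <- amplitude / sqrt(nVolumes)
    for (j in 1:3) {
      trace[-1, j] <- cumsum(stats::rnorm(nVolumes - 1, 0, step))
    }
    for (j in 4:6) {  # radians; ~amplitude mm of arc at 50 mm radius
      trace[-1, j] <- cumsum(stats::rnorm(nVolumes - 1, 0, step / 50))
    }
  }
  trace
}
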