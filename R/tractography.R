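# Streamline tractography: Euler integration along the principal
# eigenvector of a trilinearly interpolated tensor field, with FA,
# curvature, mask and step-count termination rules.

# trilinear interpolation of the 6 tensor components at mm point p;
# voxel i's centre sits at (i - 0.5) * voxelSize
.interpTensor <- function(tensor, p, vs) {
  d <- dim(tensor)[1:3]
  f <- p / vs + 0.5
  i0 <- pmin(pmax(floor(f), 1), d)
  i1 <- pmin(i0 + 1, d)
  w <- pmin(pmax(f - i0, 0), 1)
  out <- numeric(6)
  for (cx in 0:1) {
    for (cy in 0:1) {
      for (cz in 0:1) {
        wt <- (if (cx) w[1] else 1 - w[1]) *
          (if (cy) w[2] else 1 - w[2]) *
          (if (cz) w[3] else 1 - w[3])
        if (wt == 0) next
        ix <- if (cx) i1[1] else i0[1]
        iy <- if (cy) i1[2] else i0[2]
        iz <- if (cz) i1[3] else i0[3]
        out <- out + wt * tensor[ix, iy, iz, ]
      }
    }
  }
  out
}

# principal eigenvector of the interpolated tensor at p
.fieldDirection <- function(tensor, p, vs) {
  t6 <- .interpTensor(tensor, p, vs)
  D <- matrix(c(
    t6[1], t6[4], t6[5],
    t6[4], t6[2], t6[6],
    t6[5], t6[6], t6[3]
  ), 3, 3)
  v <- eigen(D, symmetric = TRUE)$vectors[, 1]
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n == 0) return(NULL)
  v / n
}

# nearest voxel index of mm point p (1-based); NULL outside grid
.pointVoxel <- function(p, vs, d) {
  i <- floor(p / vs) + 1L
  if (any(i < 1L) || any(i > d)) return(NULL)
  as.integer(i)
}

# von Mises-Fisher sample around unit vector mu (3D, concentration kappa)
.vmfJitter <- function(mu, kappa) {
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(1, 0, 2 * pi)
  frame <- .frameFrom(mu)
  s <- sqrt(max(0, 1 - w^2))
  as.vector(frame %*% c(w, s * cos(phi), s * sin(phi)))
}

# single direction of travel from point p along the field, sign-aligned
# with prev and optionally jittered
.stepDirection <- function(tensors, p, prev, jitterKappa) {
  v <- .fieldDirection(tensors@tensor, p, tensors@voxelSize)
  if (is.null(v)) return(NULL)
  if (sum(v * prev) < 0) v <- -v
  if (jitterKappa > 0) v <- .vmfJitter(v, jitterKappa)
  v
}

# one unidirectional branch; returns points beyond the seed plus the
# termination reason
.trackBranch <- function(tensors, trackable, p0, d0, step, faFloor,
                         cosLimit, maxSteps, jitterKappa) {
  d <- dim(tensors@fa)
  vs <- tensors@voxelSize
  pts <- matrix(0, maxSteps, 3)
  n <- 0L
  p <- p0
  dir <- d0
  reason <- "max_steps"
  while (n < maxSteps) {
    pn <- p + step * dir
    vox <- .pointVoxel(pn, vs, d)
    if (is.null(vox) || !trackable[vox[1], vox[2], vox[3]]) {
      reason <- "left_mask"
      break
    }
    if (tensors@fa[vox[1], vox[2], vox[3]] < faFloor) {
      reason <- "fa_floor"
      break
    }
    n <- n + 1L
    pts[n, ] <- pn
    nd <- .stepDirection(tensors, pn, dir, jitterKappa)
    if (is.null(nd)) {
      reason <- "zero_direction"
      break
    }
    if (sum(nd * dir) < cosLimit) {
      reason <- "curvature"
      break
    }
    p <- pn
    dir <- nd
  }
  list(points = pts[seq_len(n), , drop = FALSE], reason = reason)
}

#' Track one streamline from a seed voxel
#'
#' Bidirectional deterministic (optionally direction-jittered)
#' streamline tracking: Euler integration with a fixed step along the
#' principal eigenvector of the trilinearly interpolated tensor field,
#' starting from the seed voxel centre in both antipodal directions;
#' the two branches are joined into a single streamline. Tracking
#' stops on entering a voxel below the FA floor, when the turning
#' angle between successive steps exceeds \code{maxAngleDeg}, on
#' leaving the trackable mask or grid, or at the step cap.
#'
#' @param seed integer voxel index (i, j, k), 1-based; must lie in the
#'   trackable mask and at or above the FA floor.
#' @param tensors a [TensorMaps-class].
#' @param trackable logical 3D array of voxels tracking may traverse
#'   (defaults to the fitted-voxel mask).
#' @param step step size in mm.
#' @param faFloor FA termination threshold.
#' @param maxAngleDeg curvature termination threshold in degrees.
#' @param jitterKappa von Mises-Fisher concentration for probabilistic
#'   direction jitter; 0 disables jitter (deterministic tracking).
#' @param maxSteps per-branch safety cap.
#' @return list with \code{points} (n x 3 matrix, mm), \code{seed} and
#'   \code{reasons} (termination reason of the backward and forward
#'   branches).
#' @export
trackStreamline <- function(seed, tensors, trackable = tensors@mask,
                            step = 0.5, faFloor = 0.2, maxAngleDeg = 60,
                            jitterKappa = 0, maxSteps = 2000L) {
  seed <- as.integer(seed)
  d <- dim(tensors@fa)
  if (any(seed < 1L) || any(seed > d)) stop("seed voxel outside the grid")
  if (!trackable[seed[1], seed[2], seed[3]]) {
    stop("seed voxel is outside the trackable mask")
  }
  if (tensors@fa[seed[1], seed[2], seed[3]] < faFloor) {
    stop("seed voxel FA is below the tracking floor")
  }
  vs <- tensors@voxelSize
  p0 <- (seed - 0.5) * vs
  d0 <- .fieldDirection(tensors@tensor, p0, vs)
  if (is.null(d0)) stop("zero-norm direction at the seed")
  if (jitterKappa > 0) d0 <- .vmfJitter(d0, jitterKappa)
  cosLimit <- cos(maxAngleDeg * pi / 180)

  fwd <- .trackBranch(tensors, trackable, p0, d0, step, faFloor,
                      cosLimit, maxSteps, jitterKappa)
  bwd <- .trackBranch(tensors, trackable, p0, -d0, step, faFloor,
                      cosLimit, maxSteps, jitterKappa)
  pts <- rbind(
    bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
    matrix(p0, 1, 3),
    fwd$points
  )
  list(points = pts, seed = seed,
       reasons = c(backward = bwd$reason, forward = fwd$reason))
}

#' Whole-brain exhaustive-seed tractography
#'
#' Launches one streamline (or \code{samplesPerSeed} jittered samples)
#' from the centre of every white-matter voxel whose FA reaches the
#' floor, in deterministic sorted-voxel order.
#'
#' @param tensors a [TensorMaps-class].
#' @param wmMask logical 3D white-matter seed mask.
#' @param step,faFloor,maxAngleDeg,jitterKappa,maxSteps as in
#'   [trackStreamline()].
#' @param samplesPerSeed streamlines launched per eligible seed (> 1
#'   only makes sense with jitter).
#' @param seed RNG seed applied when jitter is active.
#' @return list of streamlines (see [trackStreamline()]); empty with a
#'   warning when no voxel is eligible.
#' @export
runWholeBrain <- function(tensors, wmMask, step = 0.5, faFloor = 0.2,
                          maxAngleDeg = 60, jitterKappa = 0,
                          samplesPerSeed = 1L, maxSteps = 2000L,
                          seed = 1L) {
  if (!any(wmMask)) stop("white-matter mask is empty")
  eligible <- which(wmMask & tensors@fa >= faFloor)  # sorted linear order
  if (!length(eligible)) {
    warning("no white-matter voxel reaches the FA floor; nothing to track")
    return(list())
  }
  if (jitterKappa > 0) set.seed(as.integer(seed))
  idx <- arrayInd(eligible, dim(tensors@fa))
  out <- vector("list", length(eligible) * samplesPerSeed)
  k <- 0L
  for (r in seq_len(nrow(idx))) {
    for (s in seq_len(samplesPerSeed)) {
      k <- k + 1L
      out[[k]] <- trackStreamline(
        idx[r, ], tensors, trackable = wmMask & tensors@mask,
        step = step, faFloor = faFloor, maxAngleDeg = maxAngleDeg,
        jitterKappa = jitterKappa, maxSteps = maxSteps
      )
    }
  }
  out
}

#' Build a region-pair connectivity matrix from streamlines
#'
#' A streamline connects regions (i, j), i != j, when its point set
#' (at nearest-voxel resolution) intersects both label regions; every
#' touched pair is incremented symmetrically, and a streamline
#' touching three or more regions increments each touched pair. The
#' parallel edge weight is the mean axial diffusivity over all voxels
#' visited by all streamlines connecting the pair. Streamlines
#' touching fewer than two regions contribute nothing.
#'
#' @param streamlines list of streamlines from [runWholeBrain()].
#' @param atlas an [ROIAtlas-class] on the same grid as the maps.
#' @param adMap 3D axial-diffusivity array on the same grid.
#' @param subject subject identifier stored in the result.
#' @return a [ConnectivityMatrix-class].
#' @export
buildConnectome <- function(streamlines, atlas, adMap,
                            subject = "subject") {
  lab <- atlas@labels
  if (!identical(dim(lab), dim(adMap))) {
    stop("atlas and AD map are on different voxel grids")
  }
  vs <- atlas@voxelSize
  d <- dim(lab)
  n <- max(atlas@labelTable$label, nRegions(atlas))
  cnt <- matrix(0, n, n)
  adSum <- matrix(0, n, n)
  adN <- matrix(0, n, n)

  for (sl in streamlines) {
    pts <- sl$points
    if (is.null(pts) || nrow(pts) < 2L) next
    vox <- floor(sweep(pts, 2, vs, "/")) + 1
    vox <- pmin(pmax(vox, 1), matrix(d, nrow(vox), 3, byrow = TRUE))
    vox <- unique(vox)
    li <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
    touched <- sort(unique(lab[li]))
    touched <- touched[touched != 0L]
    if (length(touched) < 2L) next
    adTotal <- sum(adMap[li])
    nVox <- length(li)
    pairs <- utils::combn(touched, 2)
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]
      j <- pairs[2, q]
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
      adSum[i, j] <- adSum[i, j] + adTotal
      adN[i, j] <- adN[i, j] + nVox
    }
  }
  meanAD <- matrix(0, n, n)
  pos <- adN > 0
  meanAD[pos] <- adSum[pos] / adN[pos]
  meanAD <- meanAD + t(meanAD)
  new("ConnectivityMatrix", counts = cnt, meanAD = meanAD,
      subject = subject)
}
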