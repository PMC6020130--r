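#' Fit the diffusion tensor per voxel
#'
#' Ordinary least-squares fit of the log-linearized monoexponential
#' signal model ln S = ln S0 - b g' D g, solving for the six unique
#' tensor elements plus ln S0 at every masked voxel, followed by a
#' symmetric eigendecomposition. Eigenvalues are sorted descending;
#' scalar maps follow the standard conventions: AD = lambda1,
#' RD = (lambda2 + lambda3)/2, MD = mean(lambda), and
#' FA = sqrt(3/2 * sum((lambda - mean)^2) / sum(lambda^2)).
#'
#' Voxels with any non-positive signal are flagged and excluded from
#' the fitted mask. Negative eigenvalues arising from noisy fits are
#' floored at 1e-12 mm^2/s (keeping FA in [0, 1]) and flagged in the
#' \code{clamped} slot. On noiseless data the fit is exact to machine
#' precision.
#'
#' @param volume a [DiffusionVolume-class] (at least 1 b0 + 6
#'   directions).
#' @return a [TensorMaps-class].
#' @examples
#' ph <- makePhantom(phantomSpec(
#'   gridShape = c(12, 6, 4),
#'   bundles = list(straightBundle(c(3, 3, 4), c(9, 3, 4), 1.5, 1))
#' ))
#' tm <- fitTensor(ph$volume)
#' range(faMap(tm))
#' @export
fitTensor <- function(volume) {
  validObject(volume)
  bvals <- volume@bvals
  bvecs <- volume@bvecs
  nvol <- length(bvals)
  if (nvol < 7L) stop("need at least 7 volumes (1 b0 + 6 directions)")

  g <- t(bvecs)
  X <- cbind(
    1,
    -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
    -2 * bvals * g[, 1] * g[, 2],
    -2 * bvals * g[, 1] * g[, 3],
    -2 * bvals * g[, 2] * g[, 3]
  )
  qrX <- qr(X)
  if (qrX$rank < 7L) {
    stop("gradient scheme is rank-deficient: cannot determine the tensor")
  }

  gs <- dim(volume@signal)[1:3]
  nvox <- prod(gs)
  sig <- matrix(volume@signal, nvox, nvol)
  maskIdx <- which(as.vector(volume@brainMask))
  bad <- maskIdx[rowSums(sig[maskIdx, , drop = FALSE] <= 0) > 0]
  fitIdx <- setdiff(maskIdx, bad)

  ev <- matrix(0, nvox, 3)
  v1 <- matrix(0, nvox, 3)
  d6 <- matrix(0, nvox, 6)
  clamped <- logical(nvox)

  if (length(fitIdx)) {
    lnS <- t(log(sig[fitIdx, , drop = FALSE]))
    coefs <- qr.coef(qrX, lnS)  # 7 x nfit
    for (k in seq_along(fitIdx)) {
      cf <- coefs[, k]
      d6[fitIdx[k], ] <- cf[2:7]
      D <- matrix(c(
        cf[2], cf[5], cf[6],
        cf[5], cf[3], cf[7],
        cf[6], cf[7], cf[4]
      ), 3, 3)
      e <- eigen(D, symmetric = TRUE)  # eigenvalues descending
      lam <- e$values
      if (lam[3] < 0) {
        lam <- pmax(lam, 1e-12)
        clamped[fitIdx[k]] <- TRUE
      }
      ev[fitIdx[k], ] <- lam
      v1[fitIdx[k], ] <- e$vectors[, 1]
    }
  }

  sc <- .eigenScalars(ev)
  sc$fa <- pmin(sc$fa, 1)
  fitted <- logical(nvox)
  fitted[fitIdx] <- TRUE
  sc$fa[!fitted] <- 0
  sc$md[!fitted] <- 0
  sc$ad[!fitted] <- 0
  sc$rd[!fitted] <- 0

  arr3 <- function(x) array(x, dim = gs)
  new("TensorMaps",
    eigenvalues = array(ev, c(gs, 3L)), v1 = array(v1, c(gs, 3L)),
    tensor = array(d6, c(gs, 6L)),
    fa = arr3(sc$fa), md = arr3(sc$md), ad = arr3(sc$ad), rd = arr3(sc$rd),
    mask = arr3(fitted), clamped = arr3(clamped),
    voxelSize = volume@voxelSize
  )
}

#' Head-motion quality control
#'
#' Applies the motion-exclusion rule: a subject is excluded when any
#' translation parameter, or any rotation parameter converted to arc
#' displacement at a fixed head radius (displacement = angle * radius),
#' strictly exceeds the limit. With the defaults this is the
#' "1.5 mm/degree-equivalent at 50 mm radius" rule; a maximum of
#' exactly 1.5 mm is retained.
#'
#' @param trace motion matrix from [makeMotionTrace()] (or read from
#'   file): three translation columns in mm then three rotation
#'   columns in radians.
#' @param limit exclusion threshold in mm.
#' @param radius head radius (mm) used to convert rotation angles to
#'   arc displacement.
#' @return list with \code{decision} ("retain" or "exclude"),
#'   \code{maxTransMm} and \code{maxRotMm}.
#' @export
motionQC <- function(trace, limit = 1.5, radius = 50) {
  trace <- as.matrix(trace)
  if (nrow(trace) == 0L) stop("motion trace is empty")
  if (ncol(trace) != 6L) stop("motion trace must have 6 columns")
  if (any(!is.finite(trace))) stop("motion trace contains non-finite values")
  maxTrans <- max(abs(trace[, 1:3]))
  maxRot <- max(abs(trace[, 4:6])) * radius
  list(
    decision = if (maxTrans > limit || maxRot > limit) "exclude" else "retain",
    maxTransMm = maxTrans,
    maxRotMm = maxRot
  )
}

#' Total intracranial volume
#'
#' TIV as the sum of grey- and white-matter volumes (mm^3); used
#' downstream as a nuisance covariate for streamline-count networks.
#'
#' @param gmVolume,wmVolume tissue volumes in mm^3 (nonnegative).
#' @return TIV in mm^3.
#' @export
computeTIV <- function(gmVolume, wmVolume) {
  if (gmVolume < 0 || wmVolume < 0) stop("tissue volumes must be nonnegative")
  gmVolume + wmVolume
}

#' Volume of a binary mask in mm^3
#'
#' @param mask logical array.
#' @param voxelSize voxel dimensions in mm.
#' @return voxel count times voxel volume (mm^3).
#' @export
maskVolume <- function(mask, voxelSize) {
  sum(mask) * prod(voxelSize)
}
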