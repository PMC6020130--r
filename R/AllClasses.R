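#' @import methods
NULL

#' DiffusionVolume: a 4D diffusion-weighted acquisition
#'
#' Container for a diffusion-weighted MRI series: the 4D signal array
#' (x, y, z, volume), the diffusion-encoding gradient table (unit
#' direction vectors and b-values per volume), the voxel geometry and a
#' brain mask. Exactly one volume must be unweighted (b = 0); it
#' provides the baseline signal for tensor fitting.
#'
#' @slot signal 4D numeric array, one 3D volume per gradient direction.
#' @slot bvals numeric vector of b-values (s/mm^2), one per volume.
#' @slot bvecs 3 x V numeric matrix of gradient directions; columns for
#'   b > 0 volumes must have unit norm.
#' @slot voxelSize numeric length-3 voxel dimensions in mm.
#' @slot brainMask logical 3D array marking voxels to fit.
#'
#' @seealso [makePhantom()], [fitTensor()], [readDiffusionVolume()]
#' @export
setClass("DiffusionVolume",
  slots = c(
    signal = "array",
    bvals = "numeric",
    bvecs = "matrix",
    voxelSize = "numeric",
    brainMask = "array"
  )
)

setValidity("DiffusionVolume", function(object) {
  d <- dim(object@signal)
  msg <- character()
  if (length(d) != 4L) {
    msg <- c(msg, "signal must be a 4D array (x, y, z, volume)")
  } else {
    if (length(object@bvals) != d[4]) {
      msg <- c(msg, "length(bvals) must equal the number of volumes")
    }
    if (!all(dim(object@bvecs) == c(3L, d[4]))) {
      msg <- c(msg, "bvecs must be a 3 x nVolumes matrix")
    }
    if (!identical(dim(object@brainMask), d[1:3])) {
      msg <- c(msg, "brainMask dimensions must match the signal grid")
    }
  }
  if (sum(object@bvals == 0) != 1L) {
    msg <- c(msg, "exactly one b = 0 volume is required")
  }
  dw <- which(object@bvals > 0)
  if (length(dw) && ncol(object@bvecs) >= max(dw)) {
    nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      msg <- c(msg, "gradient directions for b > 0 volumes must be unit vectors")
    }
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0)) {
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' TensorMaps: per-voxel diffusion tensor eigensystem and scalar maps
#'
#' Result of a tensor fit (or the ground truth stored by the phantom
#' generator): sorted eigenvalues, the principal eigenvector, and the
#' four derived scalar maps. Invariants: AD = lambda1,
#' RD = (lambda2 + lambda3)/2, MD = mean(lambda), FA in [0, 1].
#'
#' @slot eigenvalues 4D array (x, y, z, 3), sorted descending per voxel
#'   (mm^2/s).
#' @slot v1 4D array (x, y, z, 3): principal eigenvector per voxel.
#' @slot tensor 4D array (x, y, z, 6): unique tensor elements
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), kept so the tracking stage can
#'   interpolate the tensor field smoothly.
#' @slot fa,md,ad,rd 3D scalar maps (FA unitless, others mm^2/s).
#' @slot mask logical 3D array of voxels with a valid fit.
#' @slot clamped logical 3D array flagging voxels whose negative
#'   eigenvalues were floored before scalar computation.
#' @slot voxelSize numeric length-3 voxel dimensions in mm.
#' @export
setClass("TensorMaps",
  slots = c(
    eigenvalues = "array",
    v1 = "array",
    tensor = "array",
    fa = "array",
    md = "array",
    ad = "array",
    rd = "array",
    mask = "array",
    clamped = "array",
    voxelSize = "numeric"
  )
)

setValidity("TensorMaps", function(object) {
  d <- dim(object@fa)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "fa must be a 3D array")
  for (s in c("md", "ad", "rd", "mask", "clamped")) {
    if (!identical(dim(slot(object, s)), d)) {
      msg <- c(msg, sprintf("%s dimensions must match fa", s))
    }
  }
  if (!identical(dim(object@eigenvalues), c(d, 3L))) {
    msg <- c(msg, "eigenvalues must be (x, y, z, 3)")
  }
  if (!identical(dim(object@v1), c(d, 3L))) {
    msg <- c(msg, "v1 must be (x, y, z, 3)")
  }
  if (!identical(dim(object@tensor), c(d, 6L))) {
    msg <- c(msg, "tensor must be (x, y, z, 6)")
  }
  fa <- object@fa[object@mask]
  if (length(fa) && any(!is.na(fa) & (fa < -1e-12 | fa > 1 + 1e-12))) {
    msg <- c(msg, "FA must lie in [0, 1] inside the mask")
  }
  if (length(msg)) msg else TRUE
})

#' ROIAtlas: integer-labelled region-of-interest volume
#'
#' A label volume (0 = background, 1..n = regions) plus a table naming
#' each region with its hemisphere and anatomical system. The study
#' design uses 24 regions (12 bilateral ROIs over sensorimotor,
#' basal-ganglia and insular systems; see [roiLabelTable()]); phantom
#' atlases may carry fewer (two endpoint regions per bundle).
#' Regions are spatially disjoint by construction (one label per voxel).
#'
#' @slot labels integer 3D array of region labels.
#' @slot labelTable data.frame with columns label, name, hemisphere,
#'   system.
#' @slot voxelSize numeric length-3 voxel dimensions in mm.
#' @export
setClass("ROIAtlas",
  slots = c(
    labels = "array",
    labelTable = "data.frame",
    voxelSize = "numeric"
  )
)

setValidity("ROIAtlas", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) {
    msg <- c(msg, "labels must be a 3D array")
  }
  lab <- sort(unique(as.integer(object@labels)))
  lab <- lab[lab != 0L]
  if (length(lab)) {
    if (!identical(lab, seq_len(max(lab)))) {
      msg <- c(msg, "nonzero labels must be consecutive 1..n")
    }
    if (!all(lab %in% object@labelTable$label)) {
      msg <- c(msg, "labelTable must describe every label present")
    }
  }
  need <- c("label", "name", "hemisphere", "system")
  if (!all(need %in% names(object@labelTable))) {
    msg <- c(msg, "labelTable needs columns label, name, hemisphere, system")
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: a subject's structural connectome
#'
#' Symmetric n x n matrices over the atlas regions: streamline counts
#' and, in parallel, the mean axial diffusivity (AD, mm^2/s) of the
#' tract connecting each region pair. Diagonals are zero and
#' \code{meanAD > 0} exactly where \code{counts > 0}.
#'
#' @slot counts symmetric nonnegative integer-valued matrix.
#' @slot meanAD symmetric nonnegative matrix, zero where counts is zero.
#' @slot subject character scalar subject identifier.
#' @export
setClass("ConnectivityMatrix",
  slots = c(
    counts = "matrix",
    meanAD = "matrix",
    subject = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  cm <- object@counts
  am <- object@meanAD
  if (nrow(cm) != ncol(cm)) msg <- c(msg, "counts must be square")
  if (!identical(dim(cm), dim(am))) {
    msg <- c(msg, "counts and meanAD must have identical dimensions")
  } else {
    if (any(abs(cm - t(cm)) > 1e-9)) msg <- c(msg, "counts must be symmetric")
    if (any(abs(am - t(am)) > 1e-9)) msg <- c(msg, "meanAD must be symmetric")
    if (any(diag(cm) != 0) || any(diag(am) != 0)) {
      msg <- c(msg, "diagonals must be zero")
    }
    if (any(cm < 0) || any(am < 0)) msg <- c(msg, "weights must be nonnegative")
    if (any(abs(cm - round(cm)) > 1e-9)) {
      msg <- c(msg, "counts must be integer-valued")
    }
    if (any(am[cm == 0] != 0) || any(am[cm > 0] <= 0)) {
      msg <- c(msg, "meanAD must be positive exactly where counts are positive")
    }
  }
  if (length(object@subject) != 1L) msg <- c(msg, "subject must be length 1")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: recipe for a synthetic diffusion phantom
#'
#' Describes a rectangular grid holding one or more straight
#' white-matter bundles embedded in an isotropic background. Each
#' bundle is a cylinder given by start/end points (mm), a radius, the
#' three tensor eigenvalues along/across its axis, and an integer
#' bundle label; its two end caps become ROI atlas regions 2*label - 1
#' and 2*label.
#'
#' @slot gridShape integer length-3 grid dimensions (voxels).
#' @slot voxelSize numeric length-3 voxel size in mm (default 1 x 1 x 2).
#' @slot bundles list of bundles; each a list with elements
#'   \code{start}, \code{end} (mm), \code{radius} (mm), \code{evals}
#'   (three eigenvalues, mm^2/s, descending) and \code{label}.
#' @slot background isotropic background diffusivity (mm^2/s).
#' @slot bValue diffusion weighting (s/mm^2).
#' @slot nDirections number of gradient directions (>= 6).
#' @slot s0 baseline (b = 0) signal, arbitrary units.
#' @slot noiseSigma Rician noise scale per channel; 0 for noiseless.
#' @slot seed integer RNG seed for the noise.
#' @export
setClass("PhantomSpec",
  slots = c(
    gridShape = "integer",
    voxelSize = "numeric",
    bundles = "list",
    background = "numeric",
    bValue = "numeric",
    nDirections = "integer",
    s0 = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L)) {
    msg <- c(msg, "gridShape must be three positive integers")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0)) {
    msg <- c(msg, "voxelSize must be three positive lengths")
  }
  if (object@nDirections < 6L) {
    msg <- c(msg, "at least 6 gradient directions are required")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@background <= 0) msg <- c(msg, "background diffusivity must be > 0")
  for (b in object@bundles) {
    ev <- b$evals
    if (length(ev) != 3L || any(diff(ev) > 0) || any(ev <= 0)) {
      msg <- c(msg, "bundle eigenvalues must satisfy l1 >= l2 >= l3 > 0")
      break
    }
  }
  labs <- vapply(object@bundles, function(b) as.integer(b$label), integer(1))
  if (anyDuplicated(labs)) msg <- c(msg, "bundle labels must be distinct")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: recipe for a synthetic two-group connectome cohort
#'
#' Describes the statistical structure of a simulated case/control
#' cohort of 24-node structural connectomes: a log-normal baseline
#' edge-weight law shared by everyone, hub nodes with inflated
#' connection strength in both groups, an optional group difference
#' planted in one nodal graph metric at a standardized effect size, and
#' optional linear associations between clinical scores and nodal
#' metrics after covariate adjustment. Planted effects are applied by
#' scaling the target node's incident edge weights, calibrated by
#' simulation against the cohort's own between-subject metric spread
#' (see the package vignette).
#'
#' @slot nPatients,nControls group sizes.
#' @slot nNodes number of network nodes (24).
#' @slot weightDistribution list(meanlog, sdlog) of the baseline
#'   log-normal streamline-count law.
#' @slot edgeNoiseSd between-subject log-normal edge noise SD.
#' @slot hubNodes integer node indices given elevated strength in both
#'   groups.
#' @slot hubGain multiplicative strength gain at hub nodes.
#' @slot groupEffect list(node, metric, d) or empty list for a null
#'   cohort; d is the standardized between-group effect size on the
#'   nodal metric ("betweenness", "degree", "clustering",
#'   "local_efficiency" or "path_length").
#' @slot clinicalEffects list of list(node, metric, score, effect)
#'   entries; score is "ygtss" or "puts", effect a signed standardized
#'   association strength.
#' @slot covariateRanges list(age = c(min, max), iq = c(mean, sd),
#'   tiv = c(mean, sd)).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  slots = c(
    nPatients = "integer",
    nControls = "integer",
    nNodes = "integer",
    weightDistribution = "list",
    edgeNoiseSd = "numeric",
    hubNodes = "integer",
    hubGain = "numeric",
    groupEffect = "list",
    clinicalEffects = "list",
    covariateRanges = "list",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nNodes != 24L) msg <- c(msg, "nNodes must be 24")
  if (object@nPatients < 2L || object@nControls < 2L) {
    msg <- c(msg, "both groups need at least 2 subjects")
  }
  if (length(object@hubNodes) &&
      (any(object@hubNodes < 1L) || any(object@hubNodes > object@nNodes))) {
    msg <- c(msg, "hubNodes must be node indices in 1..nNodes")
  }
  planted <- character()
  if (length(object@groupEffect)) {
    ge <- object@groupEffect
    if (!all(c("node", "metric", "d") %in% names(ge))) {
      msg <- c(msg, "groupEffect needs fields node, metric, d")
    } else {
      if (!is.finite(ge$d)) msg <- c(msg, "groupEffect d must be finite")
      planted <- c(planted, paste(ge$node, ge$metric))
    }
  }
  for (ce in object@clinicalEffects) {
    if (!all(c("node", "metric", "score", "effect") %in% names(ce))) {
      msg <- c(msg, "clinicalEffects entries need node, metric, score, effect")
      break
    }
    if (!is.finite(ce$effect)) msg <- c(msg, "clinical effect sizes must be finite")
    planted <- c(planted, paste(ce$node, ce$metric))
  }
  if (anyDuplicated(planted)) {
    msg <- c(msg, "the same node + metric cannot be planted twice")
  }
  if (!all(c("age", "iq", "tiv") %in% names(object@covariateRanges))) {
    msg <- c(msg, "covariateRanges must contain age, iq and tiv")
  }
  if (length(msg)) msg else TRUE
})
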