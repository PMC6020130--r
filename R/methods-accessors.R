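#' @rdname accessors
setMethod("counts", "ConnectivityMatrix", function(object) object@counts)

#' @rdname accessors
setMethod("meanAD", "ConnectivityMatrix", function(object) object@meanAD)

#' @rdname accessors
setMethod("subjectID", "ConnectivityMatrix", function(object) object@subject)

#' @rdname accessors
setMethod("nRegions", "ConnectivityMatrix", function(object) nrow(object@counts))

#' @rdname accessors
setMethod("faMap", "TensorMaps", function(object) object@fa)

#' @rdname accessors
setMethod("mdMap", "TensorMaps", function(object) object@md)

#' @rdname accessors
setMethod("adMap", "TensorMaps", function(object) object@ad)

#' @rdname accessors
setMethod("rdMap", "TensorMaps", function(object) object@rd)

#' @rdname accessors
setMethod("voxelSize", "TensorMaps", function(object) object@voxelSize)

#' @rdname accessors
setMethod("voxelSize", "DiffusionVolume", function(object) object@voxelSize)

#' @rdname accessors
setMethod("voxelSize", "ROIAtlas", function(object) object@voxelSize)

#' @rdname accessors
setMethod("brainMask", "DiffusionVolume", function(object) object@brainMask)

#' @rdname accessors
setMethod("labelVolume", "ROIAtlas", function(object) object@labels)

#' @rdname accessors
setMethod("labelTable", "ROIAtlas", function(object) object@labelTable)

#' @rdname accessors
setMethod("nRegions", "ROIAtlas", function(object) {
  length(setdiff(unique(as.integer(object@labels)), 0L))
})

setMethod("show", "DiffusionVolume", function(object) {
  d <- dim(object@signal)
  cat("DiffusionVolume:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "volumes\n")
  cat("  b-values:", paste(unique(object@bvals), collapse = ", "), "s/mm^2;",
      sum(object@bvals > 0), "diffusion directions\n")
  cat("  voxel size:", paste(object@voxelSize, collapse = " x "), "mm;",
      sum(object@brainMask), "masked voxels\n")
})

setMethod("show", "TensorMaps", function(object) {
  cat("TensorMaps:", paste(dim(object@fa), collapse = " x "), "grid,",
      sum(object@mask), "fitted voxels\n")
  fa <- object@fa[object@mask]
  if (length(fa)) {
    cat(sprintf("  FA range %.3f-%.3f; %d voxels eigenvalue-clamped\n",
                min(fa), max(fa), sum(object@clamped)))
  }
})

setMethod("show", "ROIAtlas", function(object) {
  cat("ROIAtlas:", nRegions(object), "regions on a",
      paste(dim(object@labels), collapse = " x "), "grid\n")
  sys <- table(object@labelTable$system)
  cat("  systems:", paste(names(sys), sys, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cm <- object@counts
  cat("ConnectivityMatrix for subject", object@subject, ":",
      nrow(cm), "x", ncol(cm), "\n")
  cat("  nonzero edges:", sum(cm[upper.tri(cm)] > 0),
      "; total streamlines:", sum(cm[upper.tri(cm)]), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "), "grid,",
      length(object@bundles), "bundle(s), b =", object@bValue,
      "s/mm^2,", object@nDirections, "directions\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatients, "patients /", object@nControls,
      "controls,", object@nNodes, "nodes\n")
  if (length(object@groupEffect)) {
    ge <- object@groupEffect
    cat(sprintf("  planted group effect: %s at node %d, d = %.2f\n",
                ge$metric, ge$node, ge$d))
  }
  if (length(object@clinicalEffects)) {
    cat("  planted clinical associations:", length(object@clinicalEffects), "\n")
  }
})
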