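#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Use these
#' rather than reaching into slots.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("meanAD", function(object) standardGeneric("meanAD"))

#' @rdname accessors
#' @export
setGeneric("faMap", function(object) standardGeneric("faMap"))

#' @rdname accessors
#' @export
setGeneric("mdMap", function(object) standardGeneric("mdMap"))

#' @rdname accessors
#' @export
setGeneric("adMap", function(object) standardGeneric("adMap"))

#' @rdname accessors
#' @export
setGeneric("rdMap", function(object) standardGeneric("rdMap"))

#' @rdname accessors
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))

#' @rdname accessors
#' @export
setGeneric("labelTable", function(object) standardGeneric("labelTable"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
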