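# Readers and writers for the standard on-disk formats: NIfTI volumes
# (via RNifti), FSL-dialect bvals/bvecs text files, and TSV tables.

.writeTSV <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write and read FSL-dialect gradient tables
#'
#' \code{bvals} is a single space-separated row; \code{bvecs} holds
#' three rows (x, y, z) of space-separated components.
#'
#' @param bvals numeric b-values.
#' @param bvecs 3 x V direction matrix.
#' @param prefix path prefix; files \code{<prefix>.bval} and
#'   \code{<prefix>.bvec} are produced.
#' @return \code{readGradients} returns list(bvals, bvecs).
#' @export
writeGradients <- function(bvals, bvecs, prefix) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  }), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname writeGradients
#' @export
readGradients <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  rows <- readLines(paste0(prefix, ".bvec"))
  bvecs <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }))
  list(bvals = bvals, bvecs = bvecs)
}

#' Write a diffusion volume to NIfTI + gradient files
#'
#' @param volume a [DiffusionVolume-class].
#' @param prefix output path prefix: writes \code{<prefix>.nii.gz},
#'   \code{<prefix>_mask.nii.gz}, \code{<prefix>.bval},
#'   \code{<prefix>.bvec}.
#' @export
writeDiffusionVolume <- function(volume, prefix) {
  sig <- volume@signal
  attr(sig, "pixdim") <- volume@voxelSize
  RNifti::writeNifti(RNifti::asNifti(sig), paste0(prefix, ".nii.gz"))
  msk <- array(as.integer(volume@brainMask), dim(volume@brainMask))
  attr(msk, "pixdim") <- volume@voxelSize
  RNifti::writeNifti(RNifti::asNifti(msk, datatype = "uint8"),
                     paste0(prefix, "_mask.nii.gz"))
  writeGradients(volume@bvals, volume@bvecs, prefix)
  invisible(prefix)
}

#' Read a diffusion volume from NIfTI + gradient files
#'
#' @param prefix path prefix as used by [writeDiffusionVolume()].
#' @return a [DiffusionVolume-class].
#' @export
readDiffusionVolume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  grad <- readGradients(prefix)
  maskFile <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(maskFile)) {
    array(RNifti::readNifti(maskFile) > 0, dim(img)[1:3])
  } else {
    array(TRUE, dim(img)[1:3])
  }
  new("DiffusionVolume",
    signal = array(as.numeric(img), dim(img)),
    bvals = grad$bvals, bvecs = grad$bvecs,
    voxelSize = RNifti::pixdim(img)[1:3],
    brainMask = mask
  )
}

#' Write tensor scalar maps as NIfTI volumes
#'
#' Writes FA, MD, AD, RD and the principal eigenvector with the
#' input's voxel geometry.
#'
#' @param tensors a [TensorMaps-class].
#' @param prefix output path prefix.
#' @export
writeScalarMaps <- function(tensors, prefix) {
  maps <- list(FA = tensors@fa, MD = tensors@md, AD = tensors@ad,
               RD = tensors@rd, V1 = tensors@v1)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    attr(m, "pixdim") <- tensors@voxelSize
    RNifti::writeNifti(RNifti::asNifti(m), paste0(prefix, "_", nm, ".nii.gz"))
  }
  invisible(prefix)
}

#' Write an ROI atlas volume and its label table
#'
#' @param atlas an [ROIAtlas-class].
#' @param prefix output path prefix: \code{<prefix>.nii.gz} (int16)
#'   and \code{<prefix>_labels.tsv}.
#' @export
writeAtlas <- function(atlas, prefix) {
  lab <- array(as.integer(atlas@labels), dim(atlas@labels))
  attr(lab, "pixdim") <- atlas@voxelSize
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"),
                     paste0(prefix, ".nii.gz"))
  .writeTSV(atlas@labelTable, paste0(prefix, "_labels.tsv"))
  invisible(prefix)
}

#' Write / read a connectivity matrix as TSV
#'
#' Writes the streamline-count and mean-AD matrices as tab-separated
#' tables whose header row carries the region names.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param prefix path prefix: \code{<prefix>_counts.tsv} and
#'   \code{<prefix>_meanAD.tsv}.
#' @param regionNames optional column names (defaults to the 24-region
#'   table when dimensions match).
#' @export
writeConnectome <- function(cm, prefix, regionNames = NULL) {
  n <- nRegions(cm)
  if (is.null(regionNames)) {
    regionNames <- if (n == 24L) roiLabelTable()$name
      else paste0("region", seq_len(n))
  }
  for (what in c("counts", "meanAD")) {
    mat <- slot(cm, what)
    colnames(mat) <- regionNames
    .writeTSV(as.data.frame(mat), paste0(prefix, "_", what, ".tsv"))
  }
  invisible(prefix)
}

#' @rdname writeConnectome
#' @param subject subject identifier for the reconstructed object.
#' @export
readConnectome <- function(prefix, subject = "subject") {
  rd <- function(what) {
    as.matrix(utils::read.table(paste0(prefix, "_", what, ".tsv"),
                                header = TRUE, sep = "\t",
                                check.names = FALSE))
  }
  cnt <- unname(rd("counts"))
  ad <- unname(rd("meanAD"))
  new("ConnectivityMatrix", counts = cnt, meanAD = ad, subject = subject)
}

#' Write / read the cohort covariate table
#'
#' TSV with header \code{subject group age iq tiv ygtss puts}.
#'
#' @param cohort cohort data.frame.
#' @param file output path.
#' @export
writeCohortTable <- function(cohort, file) {
  .writeTSV(cohort, file)
  invisible(file)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a motion-parameter trace as TSV
#'
#' @param trace 6-column motion matrix.
#' @param file output path.
#' @export
writeMotionTrace <- function(trace, file) {
  .writeTSV(as.data.frame(trace), file)
  invisible(file)
}

#' @rdname writeMotionTrace
#' @export
readMotionTrace <- function(file) {
  as.matrix(utils::read.table(file, header = TRUE, sep = "\t"))
}
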