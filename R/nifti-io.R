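# NIfTI input/output for label volumes, via RNifti. Only voxel spacing is
# interpreted from the header; sform/qform orientation is deliberately not
# handled (documented limitation of the coordinate convention).

#' Read a NIfTI label image as a LabelVolume
#'
#' Accepts integer-typed images, and float images whose values are all
#' integer-valued (lossless cast). Label values absent from `labelMap` are
#' preserved in the grid and reported with a warning.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param labelMap named integer label dictionary; defaults to
#'   [hippocampusSubfields()].
#' @return A [LabelVolume-class].
#' @export
readLabelVolume <- function(path, labelMap = hippocampusSubfields()) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L]
  if (length(dim(a)) != 3L) stop("format error: expected a 3-D label image")
  if (any(!is.finite(a)) || any(a != round(a)))
    stop("format error: non-integer label data")
  sp <- RNifti::pixdim(img)[1:3]
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("format error: missing or invalid voxel spacing")
  vol <- LabelVolume(a, spacing = sp, labelMap = labelMap)
  present <- setdiff(unique(as.vector(labelGrid(vol))), c(0L, unname(labelMap)))
  if (length(present))
    warning("label value(s) not in labelMap: ", paste(present, collapse = ", "))
  vol
}

#' Write a LabelVolume as NIfTI
#'
#' @param vol a [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  img <- RNifti::asNifti(labelGrid(vol))
  RNifti::pixdim(img) <- spacing(vol)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
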