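# NIfTI-1 volumes and displacement fields via RNifti. The affine is the
# sform (code 2), mapping 0-based voxel indices to world mm.

#' Read a 3D scalar NIfTI volume
#'
#' A 4D file with a single frame is squeezed to 3D; any other
#' dimensionality is rejected.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param background background fill value attached to the volume.
#' @return an \code{intensity_volume}.
#' @export
read_volume <- function(path, background = 0) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))  # drop RNifti image attributes
  nd <- length(dim(dat))
  if (nd == 4L && dim(dat)[4] == 1L) dat <- array(dat, dim(dat)[1:3])
  else if (nd != 3L)
    stop("expected a 3D volume, got ", nd, " dimensions in '", path, "'")
  intensity_volume(dat, aff[1:4, 1:4], background = background)
}

#' Write an intensity volume as NIfTI
#'
#' @param volume an \code{intensity_volume}.
#' @param path output .nii or .nii.gz path.
#' @param datatype NIfTI on-disk datatype (default double precision, so
#'   round-trips are bit-exact).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "intensity_volume"))
  img <- RNifti::asNifti(volume$data, datatype = datatype)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dense displacement field
#'
#' The field is stored as a 4D NIfTI with the last axis holding the 3
#' displacement components in world mm, defined on the output grid.
#'
#' @param path path to the 4D NIfTI.
#' @return a \code{displacement_field}.
#' @export
read_displacement_field <- function(path) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  dm <- dim(dat)
  if (length(dm) == 5L && dm[4] == 1L && dm[5] == 3L) {
    # ITK-style (x,y,z,1,3) vector volume
    dat <- array(dat, dm[c(1:3, 5)])
    dm <- dim(dat)
  }
  if (length(dm) != 4L || dm[4] != 3L)
    stop("displacement field must be 4D with last axis = 3, got dims ",
         paste(dm, collapse = " x "))
  aff <- unclass(RNifti::xform(img))
  displacement_field(dat, aff[1:4, 1:4])
}

#' Write a displacement field as 4D NIfTI
#'
#' @param field a \code{displacement_field}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$vectors, datatype = "double")
  RNifti::sform(img) <- structure(field$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer label volume
#'
#' @param path path to an integer NIfTI.
#' @param labels optional code-to-name table passed through.
#' @return a \code{label_volume}.
#' @export
read_label_volume <- function(path, labels = NULL) {
  vol <- read_volume(path)
  label_volume(vol$data, vol$affine, labels = labels)
}

#' Write a label volume as integer NIfTI
#'
#' @param labels a \code{label_volume}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  img <- RNifti::asNifti(labels$data, datatype = "int32")
  RNifti::sform(img) <- structure(labels$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
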