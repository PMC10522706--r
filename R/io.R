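#' Read a binary mask from a NIfTI file
#'
#' Loads a `.nii`/`.nii.gz` volume, takes the voxel spacing from the header's
#' pixdim fields, and binarises at 0.5 (values > 0.5 become foreground). A 4D
#' volume whose trailing dimensions are singleton is squeezed to 3D. Only
#' spacing enters any computation; masks are assumed pre-co-registered on a
#' common grid. The header orientation code is kept so that
#' [assert_compatible()] can warn when compared masks disagree on it.
#'
#' @param path Path to a readable NIfTI volume.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read mask: no such file '%s'", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      arr <- array(arr, dim = d[1:3])
    } else {
      stop(sprintf(
        "'%s' is %dD with non-singleton trailing dimensions; expected a 3D mask",
        path, length(d)
      ), call. = FALSE)
    }
  }
  if (length(dim(arr)) != 3L) {
    stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (anyNA(sp) || any(sp <= 0)) {
    stop(sprintf("'%s' has non-positive voxel spacing (%s)",
                 path, paste(sp, collapse = ",")), call. = FALSE)
  }
  m <- seg_mask(arr, spacing_mm = sp)
  m$orientation <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  m
}

#' Write a binary mask to a NIfTI file
#'
#' Foreground is written as 1, background as 0 (uint8), with the voxel
#' spacing preserved in the header.
#'
#' @param mask A [seg_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write mask: directory '%s' does not exist",
                 dirname(path)), call. = FALSE)
  }
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = mask$shape))
  RNifti::pixdim(img) <- mask$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
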