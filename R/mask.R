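#' Construct a 3D binary segmentation mask
#'
#' A `seg_mask` bundles a 3D voxel grid of 0/1 flags with the physical edge
#' lengths of a voxel along each axis. It is the unit of comparison for all
#' agreement metrics: volumes are derived from the voxel count and spacing,
#' distances from spacing-scaled voxel-centre coordinates.
#'
#' Any input value strictly greater than 0.5 is mapped to foreground; masks
#' are therefore safe to build from expert label maps stored as 0/1 and from
#' already-thresholded model outputs. Probabilistic outputs must be
#' thresholded explicitly by the caller.
#'
#' @param voxels A 3D numeric, integer, or logical array.
#' @param spacing_mm Numeric triple of positive voxel edge lengths in mm,
#'   one per array axis.
#' @return An object of class `seg_mask` with elements `voxels` (logical 3D
#'   array), `spacing_mm`, and `shape`.
#' @examples
#' m <- seg_mask(array(c(rep(0, 6), 1, 1), c(2, 2, 2)), spacing_mm = c(1, 1, 1))
#' volume_ml(m)
#' @export
seg_mask <- function(voxels, spacing_mm = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || anyNA(spacing_mm) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three positive numbers", call. = FALSE)
  }
  vox <- array(as.vector(voxels) > 0.5, dim = dim(voxels))
  structure(
    list(voxels = vox, spacing_mm = spacing_mm, shape = dim(vox)),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  n_fg <- sum(x$voxels)
  cat(sprintf(
    "<seg_mask> %s voxels @ (%s) mm | foreground %d voxels = %.3f ml\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$spacing_mm, trim = TRUE), collapse = ", "),
    n_fg, volume_ml(x)
  ))
  invisible(x)
}

is_seg_mask <- function(x) inherits(x, "seg_mask")

stopifnot_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is_seg_mask(x)) {
    stop(sprintf("`%s` must be a seg_mask (see seg_mask())", arg), call. = FALSE)
  }
  invisible(x)
}

#' Physical foreground volume of a mask in millilitres
#'
#' Foreground voxel count times the voxel volume
#' (product of the spacing components, mm^3), divided by 1000.
#'
#' @param mask A [seg_mask()].
#' @return Non-negative volume in ml; 0 for an empty mask.
#' @export
volume_ml <- function(mask) {
  stopifnot_mask(mask)
  sum(mask$voxels) * prod(mask$spacing_mm) / 1000
}

#' Check that two masks live on the same voxel grid
#'
#' Agreement metrics are only meaningful for co-registered masks on an
#' identical grid; no resampling is performed by this package. Shapes must
#' match exactly and spacing within relative tolerance `tol`.
#'
#' @param a,b [seg_mask()] objects.
#' @param tol Relative tolerance for the spacing comparison.
#' @return Invisibly `TRUE`; errors naming the differing field otherwise.
#' @export
assert_compatible <- function(a, b, tol = 1e-4) {
  stopifnot_mask(a)
  stopifnot_mask(b)
  if (!identical(a$shape, b$shape)) {
    stop(sprintf(
      "grid mismatch: shape (%s) vs (%s)",
      paste(a$shape, collapse = ","), paste(b$shape, collapse = ",")
    ), call. = FALSE)
  }
  rel <- abs(a$spacing_mm - b$spacing_mm) / pmax(a$spacing_mm, b$spacing_mm)
  if (any(rel > tol)) {
    stop(sprintf(
      "grid mismatch: spacing_mm (%s) vs (%s)",
      paste(a$spacing_mm, collapse = ","), paste(b$spacing_mm, collapse = ",")
    ), call. = FALSE)
  }
  # orientation is informational only: distances and volumes need spacing,
  # but differing codes usually mean the masks were not co-registered
  if (!is.null(a$orientation) && !is.null(b$orientation) &&
      !identical(a$orientation, b$orientation)) {
    warning(sprintf("masks have differing header orientations (%s vs %s)",
                    a$orientation, b$orientation))
  }
  invisible(TRUE)
}
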