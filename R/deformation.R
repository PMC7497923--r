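# Dense displacement fields: differentiable warping, the field
# regularization loss and folding diagnostics.

#' A zero (identity) deformation field
#'
#' @param size integer(3) grid size.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A [DeformationField-class] whose warp is the identity.
#' @export
zeroField <- function(size, spacing = c(1, 1, 1)) {
  DeformationField(array(0, c(size, 3L)), spacing = spacing)
}

#' Warp a volume or mask through a deformation field
#'
#' Applies `out(x) = v(x + f(x))` with the chosen interpolation and
#' edge replication outside the grid. Trilinear interpolation is used
#' for intensity volumes (and is differentiable with respect to both
#' inputs inside training); nearest-neighbour is for label masks, which
#' must not be blended.
#'
#' @param v a [Volume-class] or [ROIMask-class].
#' @param f a [DeformationField-class] on the same grid.
#' @param interpolation `"trilinear"` or `"nearest"`. Masks always use
#'   nearest.
#' @return Warped object of the same class as `v`.
#' @export
warpVolume <- function(v, f, interpolation = c("trilinear", "nearest")) {
  stopifnot(is(f, "DeformationField"))
  interpolation <- match.arg(interpolation)
  if (is(v, "ROIMask")) {
    if (!identical(dim(v@labels), dim(f@displacements)[1:3]))
      stop("warpVolume: mask and field grid dimensions differ")
    lab <- v@labels
    storage.mode(lab) <- "double"
    w <- cpp_warp_fw(lab, f@displacements, TRUE)
    return(ROIMask(array(as.integer(round(w)), dim(lab)),
                   labelNames = v@labelNames, spacing = v@spacing))
  }
  stopifnot(is(v, "Volume"))
  if (!identical(dim(v@data), dim(f@displacements)[1:3]))
    stop("warpVolume: volume and field grid dimensions differ")
  w <- cpp_warp_fw(v@data, f@displacements, interpolation == "nearest")
  Volume(w, spacing = v@spacing, origin = v@origin, modality = v@modality)
}

#' Field regularization loss
#'
#' The literal L2 penalty on the deformation: the squared displacement
#' magnitude averaged over voxels, `mean_x ||f(x)||^2` (voxel units).
#' Zero iff the field is identically zero. A first-difference (gradient)
#' penalty is available as `type = "gradient"`: the mean squared
#' forward difference, averaged over voxels, the 3 displacement
#' components and the 3 axes.
#'
#' @param f a [DeformationField-class].
#' @param type `"magnitude"` (default) or `"gradient"`.
#' @return A non-negative scalar.
#' @export
regularizationLoss <- function(f, type = c("magnitude", "gradient")) {
  stopifnot(is(f, "DeformationField"))
  type <- match.arg(type)
  u <- f@displacements
  d <- dim(u)[1:3]
  nvox <- prod(d)
  if (type == "magnitude") return(sum(u * u) / nvox)
  nterm <- 9 * nvox
  acc <- 0
  if (d[1] >= 2) {
    dif <- u[2:d[1], , , , drop = FALSE] - u[1:(d[1] - 1), , , , drop = FALSE]
    acc <- acc + sum(dif^2) / nterm
  }
  if (d[2] >= 2) {
    dif <- u[, 2:d[2], , , drop = FALSE] - u[, 1:(d[2] - 1), , , drop = FALSE]
    acc <- acc + sum(dif^2) / nterm
  }
  if (d[3] >= 2) {
    dif <- u[, , 2:d[3], , drop = FALSE] - u[, , 1:(d[3] - 1), , drop = FALSE]
    acc <- acc + sum(dif^2) / nterm
  }
  acc
}

#' Fraction of folded voxels of a deformation
#'
#' Computes the finite-difference Jacobian determinant of the mapping
#' `x + f(x)` on interior voxels and reports the fraction with
#' determinant <= 0 — locations where the deformation self-overlaps.
#'
#' @param f a [DeformationField-class], grid at least 2 voxels per axis.
#' @return Fraction in `[0, 1]`.
#' @export
jacobianFoldingFraction <- function(f) {
  stopifnot(is(f, "DeformationField"))
  if (any(dim(f@displacements)[1:3] < 2L))
    stop("grid dimensions must be >= 2 per axis")
  cpp_fold_fraction(f@displacements)
}

#' Sample a deformation field at continuous voxel coordinates
#'
#' Trilinear interpolation of each displacement component at the given
#' (0-based) voxel coordinates.
#'
#' @param f a [DeformationField-class].
#' @param coords numeric matrix (n x 3) of voxel coordinates.
#' @return numeric matrix (n x 3) of displacements in voxel units.
#' @export
sampleField <- function(f, coords) {
  stopifnot(is(f, "DeformationField"))
  coords <- as.matrix(coords)
  u <- f@displacements
  out <- vapply(1:3, function(c)
    cpp_sample_trilinear(array(u[, , , c], dim(u)[1:3]), coords),
    numeric(nrow(coords)))
  matrix(out, nrow(coords), 3)
}

#' Save a deformation field as 4D NIfTI
#'
#' Components are stored along the 4th dimension, displacements in voxel
#' units (convention noted here: `out(x) = v(x + f(x))`).
#'
#' @param f a [DeformationField-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
saveDeformationField <- function(f, path) {
  stopifnot(is(f, "DeformationField"))
  .write_nifti_array(f@displacements, f@spacing, c(0, 0, 0), path)
  invisible(path)
}

#' Load a deformation field from 4D NIfTI
#'
#' @param path path written by [saveDeformationField()].
#' @return A [DeformationField-class].
#' @export
loadDeformationField <- function(path) {
  if (!file.exists(path)) stop("cannot read field, file not found: ", path)
  raw <- .read_nifti_array(path)
  if (length(dim(raw$data)) != 4L || dim(raw$data)[4] != 3L)
    stop("not a 3-component 4D field: ", path)
  DeformationField(raw$data, spacing = raw$spacing)
}
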