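#' Displacement vector fields
#'
#' A displacement vector field (DVF) stores, for every voxel, the offset to
#' its nearest background voxel: zero on background, and
#' `(x - x', y - y', z - z')` on foreground, where `(x', y', z')` is the
#' nearest background voxel under the Euclidean metric.  The three channels
#' are kept as separate 3D arrays `dx`, `dy`, `dz` of identical shape.
#'
#' @param dx,dy,dz 3D numeric arrays of identical shape.
#' @return A `dvf_field` object.
#' @export
as_dvf <- function(dx, dy, dz) {
  dx <- as_volume(dx); dy <- as_volume(dy); dz <- as_volume(dz)
  check_same_dims(dx, dy, "DVF channels")
  check_same_dims(dx, dz, "DVF channels")
  structure(list(dx = dx, dy = dy, dz = dz), class = "dvf_field")
}

#' @export
print.dvf_field <- function(x, ...) {
  d <- dim(x$dx)
  cat(sprintf("<dvf_field> %d x %d x %d (z, y, x), max |d| = %.3f\n",
              d[1], d[2], d[3], sqrt(max(x$dx^2 + x$dy^2 + x$dz^2))))
  invisible(x)
}

#' @export
dim.dvf_field <- function(x) dim(x$dx)

#' Ground-truth displacement vector field of an instance mask
#'
#' Computes, for every foreground voxel, the displacement to its nearest
#' background voxel (exact Euclidean nearest, via a separable squared distance
#' transform).  Equidistant background voxels are tie-broken deterministically
#' to the one with the smallest `(z, y, x)` lexicographic coordinate (the
#' smallest linear index in z-major order).  Voxels outside the volume are not
#' treated as background, so cells touching the border behave as if they
#' continued past it.
#'
#' @param mask An instance mask (see [as_instance_mask()]); any non-zero label
#'   is foreground.
#' @param spacing Optional `(z, y, x)` voxel size used for the distance metric.
#'   Displacements are always returned in voxel index units.
#' @return A `dvf_field`.
#' @export
compute_dvf <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_instance_mask(mask)
  if (all(mask > 0)) abort("mask has no background voxel; a DVF is undefined")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) abort("spacing must be positive")
  d <- dim(mask)
  fg <- as.integer(mask > 0)
  dsq <- cpp_edt_sq(fg, d[1], d[2], d[3], spacing[1], spacing[2], spacing[3])
  ch <- cpp_dvf(fg, dsq, d[1], d[2], d[3], spacing[1], spacing[2], spacing[3])
  as_dvf(array(ch$dx, d), array(ch$dy, d), array(ch$dz, d))
}

#' Distance map of a displacement vector field
#'
#' The per-voxel L2 norm of the DVF.  For a ground-truth field this equals the
#' Euclidean distance transform of the foreground.
#'
#' @param field A `dvf_field`.
#' @return A 3D array of non-negative distances (voxel units).
#' @export
dvf_to_distance <- function(field) {
  stopifnot(inherits(field, "dvf_field"))
  sqrt(field$dx^2 + field$dy^2 + field$dz^2)
}

#' Loss weights for DVF regression
#'
#' The training loss is `omega1 * Ld + omega2 * Lr` with `Ld` the mean squared
#' displacement error and `Lr` the mean cosine-dissimilarity.  The defaults
#' `omega1 = 7`, `omega2 = 1` follow the published calibration.
#'
#' @param omega1,omega2 Non-negative weights, not both zero.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(omega1 = 7, omega2 = 1) {
  if (omega1 < 0 || omega2 < 0 || omega1 + omega2 <= 0) {
    abort("loss weights must be non-negative and not both zero")
  }
  structure(list(omega1 = omega1, omega2 = omega2), class = "loss_weights")
}

dvf_mat <- function(field) {
  rbind(as.vector(field$dx), as.vector(field$dy), as.vector(field$dz))
}

#' Displacement (squared error) loss
#'
#' `Ld = 1/(3N) * sum_i || d_pred,i - d_gt,i ||^2` over all `N` voxels.
#'
#' @param pred,gt `dvf_field` objects of identical shape.
#' @return A non-negative scalar, zero iff the fields are identical.
#' @export
displacement_loss <- function(pred, gt) {
  check_same_dims(pred$dx, gt$dx, "DVF fields")
  n <- length(pred$dx)
  (sum((pred$dx - gt$dx)^2) + sum((pred$dy - gt$dy)^2) +
     sum((pred$dz - gt$dz)^2)) / (3 * n)
}

#' Direction (cosine) loss
#'
#' `Lr = 1 - mean_i cos(d_pred,i, d_gt,i)` over valid voxels.  Voxels where
#' either vector has norm `<= eps` (in particular all background voxels of the
#' ground truth, whose vector is exactly zero) are excluded: the cosine is
#' undefined at zero norm, and padding the denominator would bias background
#' toward arbitrary directions.
#'
#' @param pred,gt `dvf_field` objects of identical shape.
#' @param eps Norm threshold below which a vector counts as zero.
#' @return A scalar in `[0, 2]`; `0` when no voxel is valid (with a warning).
#' @export
direction_loss <- function(pred, gt, eps = 1e-8) {
  check_same_dims(pred$dx, gt$dx, "DVF fields")
  p <- dvf_mat(pred); g <- dvf_mat(gt)
  np <- sqrt(colSums(p^2)); ng <- sqrt(colSums(g^2))
  valid <- np > eps & ng > eps
  if (!any(valid)) {
    warn("no voxel with non-zero vectors in both fields; direction loss is 0")
    return(0)
  }
  cosv <- colSums(p[, valid, drop = FALSE] * g[, valid, drop = FALSE]) /
    (np[valid] * ng[valid])
  1 - mean(cosv)
}

#' Combined DVF regression loss
#'
#' @inheritParams direction_loss
#' @param w A [loss_weights()] object.
#' @return `omega1 * Ld + omega2 * Lr`.
#' @export
total_loss <- function(pred, gt, w = loss_weights(), eps = 1e-8) {
  w$omega1 * displacement_loss(pred, gt) + w$omega2 * direction_loss(pred, gt, eps)
}
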