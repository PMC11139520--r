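#' Validate and coerce a 3D intensity volume
#'
#' Volumes are plain 3D numeric arrays with `dim = c(nz, ny, nx)`, indexed
#' `[z, y, x]`.  World coordinates used by the point-set side of the package
#' are `(x, y, z)` in voxel units with 1-based voxel centres; see
#' [grid_to_xyz()].
#'
#' @param x A 3D numeric array (a 2D matrix is promoted to a depth-1 volume).
#' @return The validated array.
#' @export
as_volume <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("a volume must be a 3D array with dim = (nz, ny, nx)")
  }
  if (!is.numeric(x)) abort("a volume must be numeric")
  x
}

#' Validate an instance-label mask
#'
#' Instance masks are 3D integer arrays: `0` marks background, positive
#' integers mark cell instances.
#'
#' @param x A 3D array of non-negative integers.
#' @return The validated integer array.
#' @export
as_instance_mask <- function(x) {
  x <- as_volume(x)
  if (any(x < 0)) abort("instance labels must be non-negative integers")
  if (any(x != round(x))) abort("instance labels must be integers")
  storage.mode(x) <- "integer"
  x
}

#' Convert between grid indices and world coordinates
#'
#' Grid arrays are indexed `[z, y, x]` (1-based); point sets carry `(x, y, z)`
#' columns in voxel units.  These helpers are the single place where the two
#' conventions meet.
#'
#' @param zyx A matrix with columns `z, y, x` of 1-based voxel indices.
#' @return A matrix with columns `x, y, z`.
#' @export
grid_to_xyz <- function(zyx) {
  zyx <- rbind(zyx)
  out <- zyx[, c(3L, 2L, 1L), drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' @rdname grid_to_xyz
#' @param xyz A matrix with columns `x, y, z`.
#' @export
xyz_to_grid <- function(xyz) {
  xyz <- rbind(xyz)
  out <- xyz[, c(3L, 2L, 1L), drop = FALSE]
  colnames(out) <- c("z", "y", "x")
  out
}

#' Separable Gaussian blur of a 3D volume
#'
#' @param vol A 3D array.
#' @param sigma Gaussian standard deviation in voxels (scalar or per-axis
#'   `(z, y, x)` vector).
#' @return The blurred array.
#' @export
gauss_blur3d <- function(vol, sigma = 1) {
  vol <- as_volume(vol)
  sigma <- rep_len(sigma, 3L)
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    n <- d[ax]
    # band matrix applying the kernel along axis `ax` with edge renormalisation
    band <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      band[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    v <- aperm(vol, perm)
    dd <- dim(v)
    v <- band %*% matrix(v, nrow = dd[1])
    v <- array(v, dd)
    vol <- aperm(v, order(perm))
  }
  vol
}

linear_index_count <- function(dims) prod(dims)

check_same_dims <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must share the same dimensions", what))
  }
  invisible(TRUE)
}
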