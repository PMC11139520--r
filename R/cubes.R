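#' Cube partitioning specification
#'
#' Large stacks are processed in fixed-size cubes.  `shape` and `stride` are
#' `(z, y, x)` triples; with `stride < shape` neighbouring cubes overlap and
#' predictions are mean-blended on reassembly.
#'
#' @param shape Cube shape `(nz, ny, nx)`.
#' @param stride Step between cube origins; defaults to `shape` (no overlap).
#' @return A `cube_spec` object.
#' @export
cube_spec <- function(shape = c(16L, 32L, 32L), stride = shape) {
  shape <- as.integer(rep_len(shape, 3L))
  stride <- as.integer(rep_len(stride, 3L))
  if (any(stride <= 0) || any(stride > shape)) {
    abort("stride must satisfy 0 < stride <= shape componentwise")
  }
  structure(list(shape = shape, stride = stride), class = "cube_spec")
}

#' Partition a volume into cubes on a regular grid
#'
#' Cube origins form a regular grid at `spec$stride`; the grid is chosen so
#' that the cubes cover the whole volume, and cubes protruding past the far
#' border are zero-padded to `spec$shape`.
#'
#' @param vol A 3D array (or a 4D `(channels, z, y, x)` array, partitioned
#'   channel-consistently).
#' @param spec A [cube_spec()].
#' @return A tibble with columns `oz, oy, ox` (1-based cube origins) and a
#'   list-column `cube`.
#' @export
partition_volume <- function(vol, spec = cube_spec()) {
  has_ch <- length(dim(vol)) == 4L
  d <- if (has_ch) dim(vol)[-1] else dim(as_volume(vol))
  # origin grid at `stride`; the trailing cube on each axis is zero-padded,
  # and an extra flush start is never needed because padding is cropped on
  # reassembly
  starts <- function(n, st) {
    s <- seq.int(1L, n, by = st)
    s[s <= n]
  }
  origins <- expand.grid(oz = starts(d[1], spec$stride[1]),
                         oy = starts(d[2], spec$stride[2]),
                         ox = starts(d[3], spec$stride[3]),
                         KEEP.OUT.ATTRS = FALSE)
  cubes <- purrr::pmap(origins, function(oz, oy, ox) {
    crop_pad(vol, c(oz, oy, ox), spec$shape, has_ch)
  })
  out <- as_tibble(origins)
  out$cube <- cubes
  out
}

crop_pad <- function(vol, origin, shape, has_ch) {
  d <- if (has_ch) dim(vol)[-1] else dim(vol)
  ez <- min(origin[1] + shape[1] - 1L, d[1])
  ey <- min(origin[2] + shape[2] - 1L, d[2])
  ex <- min(origin[3] + shape[3] - 1L, d[3])
  if (has_ch) {
    cube <- array(0, c(dim(vol)[1], shape))
    cube[, seq_len(ez - origin[1] + 1L), seq_len(ey - origin[2] + 1L),
         seq_len(ex - origin[3] + 1L)] <-
      vol[, origin[1]:ez, origin[2]:ey, origin[3]:ex, drop = FALSE]
  } else {
    cube <- array(0, shape)
    cube[seq_len(ez - origin[1] + 1L), seq_len(ey - origin[2] + 1L),
         seq_len(ex - origin[3] + 1L)] <-
      vol[origin[1]:ez, origin[2]:ey, origin[3]:ex, drop = FALSE]
  }
  cube
}

#' Reassemble cubes into a volume
#'
#' Inverse of [partition_volume()]: cubes are placed back at their origins,
#' overlapping voxels are averaged, and padding past the volume border is
#' cropped.
#'
#' @param pieces A tibble as returned by [partition_volume()] (columns
#'   `oz, oy, ox, cube`); cubes may be 3D or 4D `(channels, ...)`.
#' @param out_shape Target `(nz, ny, nx)`.
#' @return A 3D array, or 4D `(channels, nz, ny, nx)` when cubes carry
#'   channels.
#' @export
assemble_cubes <- function(pieces, out_shape) {
  stopifnot(nrow(pieces) > 0)
  has_ch <- length(dim(pieces$cube[[1]])) == 4L
  nch <- if (has_ch) dim(pieces$cube[[1]])[1] else 1L
  acc <- array(0, c(nch, out_shape))
  cnt <- array(0, out_shape)
  for (i in seq_len(nrow(pieces))) {
    cube <- pieces$cube[[i]]
    if (!has_ch) cube <- array(cube, c(1L, dim(cube)))
    o <- c(pieces$oz[i], pieces$oy[i], pieces$ox[i])
    sh <- dim(cube)[-1]
    ez <- min(o[1] + sh[1] - 1L, out_shape[1])
    ey <- min(o[2] + sh[2] - 1L, out_shape[2])
    ex <- min(o[3] + sh[3] - 1L, out_shape[3])
    lz <- ez - o[1] + 1L; ly <- ey - o[2] + 1L; lx <- ex - o[3] + 1L
    blk <- acc[, o[1]:ez, o[2]:ey, o[3]:ex, drop = FALSE] +
      cube[, seq_len(lz), seq_len(ly), seq_len(lx), drop = FALSE]
    acc[, o[1]:ez, o[2]:ey, o[3]:ex] <- blk
    cnt[o[1]:ez, o[2]:ey, o[3]:ex] <- cnt[o[1]:ez, o[2]:ey, o[3]:ex] + 1
  }
  if (any(cnt == 0)) abort("cubes do not cover the requested output shape")
  for (ch in seq_len(nch)) acc[ch, , , ] <- acc[ch, , , ] / cnt
  if (has_ch) acc else array(acc[1, , , ], out_shape)
}
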