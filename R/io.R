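#' Read and write 3D volumes as multi-page TIFF
#'
#' Intensity volumes are stored as 32-bit float TIFF pages (one page per z
#' slice); label masks as 16-bit integer pages, automatically promoted to
#' 32-bit float storage when the maximum label exceeds 65535.  Round trips
#' are lossless for these types.
#'
#' @param path File path.
#' @param vol A 3D array.
#' @return `read_volume()` returns a 3D array `(z, y, x)`; a 2D TIFF yields a
#'   depth-1 volume.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read TIFF: '%s' does not exist", path))
  # as.is returns raw integer samples; float pages are always returned
  # natively and reject as.is
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]])[1:2])
  vol <- array(0, d)
  for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
  vol
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  write_float_tiff(lapply(seq_len(dim(vol)[1]), function(i) vol[i, , ]), path)
  invisible(path)
}

# Minimal multi-page 32-bit IEEE-float TIFF writer (little-endian, one strip
# per page).  The tiff package reads float TIFFs but only writes [0,1]-scaled
# integer samples, which cannot hold displacement fields losslessly.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(8L)  # first IFD directly after the header
  pos <- 8
  n_entries <- 10L
  ifd_size <- 2 + 12 * n_entries + 4
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); wd <- ncol(m)
    nbytes <- 4 * h * wd
    data_off <- pos + ifd_size
    w16(n_entries)
    entry(256L, 3L, 1L, wd)           # ImageWidth
    entry(257L, 3L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)          # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)    # StripOffsets
    entry(277L, 3L, 1L, 1L)          # SamplesPerPixel
    entry(278L, 3L, 1L, h)           # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)      # StripByteCounts
    entry(339L, 3L, 1L, 3L)          # SampleFormat: IEEE float
    next_ifd <- if (p < length(pages)) data_off + nbytes else 0L
    w32(next_ifd)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    pos <- data_off + nbytes
  }
  invisible(path)
}

#' @rdname read_volume
#' @param mask An instance mask.
#' @export
read_labels <- function(path) {
  vol <- read_volume(path)
  as_instance_mask(array(as.integer(round(vol)), dim(vol)))
}

#' @rdname read_volume
#' @export
write_labels <- function(mask, path) {
  mask <- as_instance_mask(mask)
  mx <- max(mask)
  if (mx <= 65535L) {
    pages <- lapply(seq_len(dim(mask)[1]), function(i) {
      m <- mask[i, , ] / 65535
      storage.mode(m) <- "double"
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    write_volume(array(as.numeric(mask), dim(mask)), path)
  }
  invisible(path)
}

#' Read/write cell point sets as CSV
#'
#' The file convention is `id,x,y,z` with coordinates in voxel units
#' (`x, y, z` order, matching the displacement-vector symbol order); the
#' in-memory grid convention is `(z, y, x)` and the conversion lives in
#' [grid_to_xyz()] alone.
#'
#' @param path File path.
#' @param points A `cell_points` tibble.
#' @return `read_points()` returns a `cell_points` tibble.
#' @export
read_points <- function(path) {
  df <- read.csv(path, strip.white = TRUE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort("point CSV must have columns id,x,y,z")
  }
  cell_points(df)
}

#' @rdname read_points
#' @export
write_points <- function(points, path) {
  points <- cell_points(points)
  write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a statistical atlas to JSON
#'
#' The atlas table, shape-context parameters, reference histograms and
#' orientation frame round-trip losslessly (within double precision).
#'
#' @param atlas A `cell_atlas`.
#' @param path File path.
#' @return `read_atlas()` returns a `cell_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "cell_atlas"))
  obj <- list(
    ids = atlas$id,
    asp = pts_mat(atlas),
    spv = as.matrix(atlas[, c("sx", "sy", "sz")]),
    tsv = atlas$gamma,
    sc_ref = attr(atlas, "sc_ref"),
    sc_params = unclass(attr(atlas, "sc_params")),
    frame = attr(atlas, "frame"),
    build = attr(atlas, "build")
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  at <- cell_points(tibble(
    id = obj$ids, x = obj$asp[, 1], y = obj$asp[, 2], z = obj$asp[, 3]
  ))
  at$sx <- obj$spv[, 1]; at$sy <- obj$spv[, 2]; at$sz <- obj$spv[, 3]
  at$gamma <- obj$tsv
  attr(at, "sc_ref") <- as.matrix(obj$sc_ref)
  p <- obj$sc_params
  attr(at, "sc_params") <- shape_context_params(p$R, p$F, p$r_min, p$r_max)
  attr(at, "frame") <- as.matrix(obj$frame)
  attr(at, "build") <- obj$build
  class(at) <- c("cell_atlas", class(at))
  at
}
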