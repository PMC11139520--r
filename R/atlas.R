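#' Cell point sets
#'
#' A cell point set is a tibble with an `id` column (unique identity labels,
#' may be `NA` for unidentified cells) and `x`, `y`, `z` coordinates in voxel
#' units.
#'
#' @param df A data frame with columns `id`, `x`, `y`, `z` (or just
#'   `x, y, z`).
#' @return A `cell_points` tibble.
#' @export
cell_points <- function(df) {
  df <- as_tibble(df)
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort("cell points need x, y, z columns")
  }
  if (!"id" %in% names(df)) df$id <- NA_character_
  df$id <- as.character(df$id)
  if (anyDuplicated(stats::na.omit(df$id))) {
    dup <- df$id[duplicated(df$id) & !is.na(df$id)][1]
    abort(sprintf("duplicate cell id: '%s'", dup))
  }
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    abort("cell coordinates must be finite")
  }
  df <- df[, c("id", "x", "y", "z", setdiff(names(df), c("id", "x", "y", "z")))]
  class(df) <- c("cell_points", class(df))
  df
}

pts_mat <- function(ps) as.matrix(ps[, c("x", "y", "z")])

set_pts <- function(ps, m) {
  ps$x <- m[, 1]; ps$y <- m[, 2]; ps$z <- m[, 3]
  ps
}

#' Affine transforms on 3D point sets
#'
#' @param A A 3x3 matrix.
#' @param t A length-3 translation.
#' @return An `affine3d` object; apply with [apply_transform()].
#' @export
affine3d <- function(A = diag(3), t = c(0, 0, 0)) {
  structure(list(A = A, t = as.numeric(t)), class = "affine3d")
}

#' Apply a fitted spatial transform to a point set
#'
#' @param points A `cell_points` tibble (or an n x 3 matrix).
#' @param tf An `affine3d` or `pwa3d` transform.
#' @return The transformed points, same type as the input.
#' @export
apply_transform <- function(points, tf) UseMethod("apply_transform", tf)

#' @export
apply_transform.affine3d <- function(points, tf) {
  m <- if (is.matrix(points)) points else pts_mat(points)
  out <- sweep(m %*% t(tf$A), 2, tf$t, "+")
  if (is.matrix(points)) out else set_pts(points, out)
}

#' Least-squares affine fit between corresponding points
#'
#' Minimises `sum || A s + t - d ||^2` over the correspondences; recovers an
#' exact transform when the correspondences are affine-consistent.
#'
#' @param src,dst `cell_points` tibbles (or n x 3 matrices).
#' @param correspondences Optional two-column matrix/data frame of (src row,
#'   dst row) indices; by default rows are matched by shared `id`.
#' @param weights Optional non-negative per-correspondence weights.
#' @return An `affine3d`.
#' @export
fit_affine <- function(src, dst, correspondences = NULL, weights = NULL) {
  cc <- resolve_correspondences(src, dst, correspondences)
  S <- (if (is.matrix(src)) src else pts_mat(src))[cc[, 1], , drop = FALSE]
  D <- (if (is.matrix(dst)) dst else pts_mat(dst))[cc[, 2], , drop = FALSE]
  if (nrow(S) < 4) abort("at least 4 correspondences are required")
  X <- cbind(S, 1)
  if (!is.null(weights)) {
    w <- sqrt(weights)
    X <- X * w
    D <- D * w
  }
  if (qr(X)$rank < 4) abort("degenerate (coplanar) correspondence configuration")
  B <- unname(qr.solve(X, D))  # 4 x 3
  affine3d(A = t(B[1:3, , drop = FALSE]), t = B[4, ])
}

resolve_correspondences <- function(src, dst, correspondences) {
  if (!is.null(correspondences)) {
    cc <- as.matrix(correspondences)[, 1:2, drop = FALSE]
    storage.mode(cc) <- "integer"
    return(cc)
  }
  if (is.matrix(src) || is.matrix(dst)) {
    n <- nrow(src)
    if (n != nrow(dst)) abort("matrix inputs need explicit correspondences")
    return(cbind(seq_len(n), seq_len(n)))
  }
  shared <- intersect(src$id[!is.na(src$id)], dst$id[!is.na(dst$id)])
  if (length(shared) == 0) abort("no shared ids between the point sets")
  cbind(match(shared, src$id), match(shared, dst$id))
}

#' Piecewise affine (PWA) transform
#'
#' The source is partitioned into `n_segments` intervals along its longest
#' principal axis; an affine map is fitted per segment (on correspondences in
#' the segment window, expanded by `overlap`), and a point is mapped by
#' linearly cross-fading between the affines of the two segment centres that
#' bracket its axial position.  With `n_segments = 1` this reduces exactly to
#' [fit_affine()].  Segments with fewer than 4 usable correspondences are
#' widened until they have enough (with a warning).
#'
#' @inheritParams fit_affine
#' @param n_segments Number of axial segments.
#' @param overlap Fractional window expansion shared by neighbouring
#'   segments.
#' @return A `pwa3d` object; apply with [apply_transform()].
#' @export
fit_pwa <- function(src, dst, correspondences = NULL, n_segments = 8L,
                    overlap = 0.2) {
  cc <- resolve_correspondences(src, dst, correspondences)
  S <- (if (is.matrix(src)) src else pts_mat(src))
  D <- (if (is.matrix(dst)) dst else pts_mat(dst))
  Sc <- S[cc[, 1], , drop = FALSE]
  Dc <- D[cc[, 2], , drop = FALSE]
  ctr <- colMeans(Sc)
  ax <- prcomp(Sc, center = TRUE)$rotation[, 1]
  proj <- as.numeric(sweep(Sc, 2, ctr) %*% ax)
  rng <- range(proj)
  n_segments <- max(1L, as.integer(n_segments))
  w <- diff(rng) / n_segments
  centers <- rng[1] + (seq_len(n_segments) - 0.5) * w
  fits <- vector("list", n_segments)
  for (k in seq_len(n_segments)) {
    half <- w / 2 + overlap * w
    repeat {
      inwin <- abs(proj - centers[k]) <= half
      if (sum(inwin) >= 4 &&
          qr(cbind(Sc[inwin, , drop = FALSE], 1))$rank == 4) break
      half <- half * 1.5
      if (half > diff(rng) * 2) {
        warn("under-populated PWA segment widened to the full axis")
        inwin <- rep(TRUE, length(proj))
        break
      }
    }
    if (sum(inwin) < sum(abs(proj - centers[k]) <= w / 2 + overlap * w)) {
      # unreachable; kept for clarity
    }
    fits[[k]] <- fit_affine(Sc[inwin, , drop = FALSE], Dc[inwin, , drop = FALSE],
                            correspondences = cbind(seq_len(sum(inwin)),
                                                    seq_len(sum(inwin))))
  }
  structure(list(axis = ax, center = ctr, centers = centers, fits = fits),
            class = "pwa3d")
}

# per-point cross-fade weights over the two bracketing segment affines
pwa_blend <- function(tf, m) {
  proj <- as.numeric(sweep(m, 2, tf$center) %*% tf$axis)
  K <- length(tf$centers)
  k1 <- k2 <- integer(nrow(m))
  a <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- proj[i]
    if (K == 1 || p <= tf$centers[1]) {
      k1[i] <- k2[i] <- 1L; a[i] <- 0
    } else if (p >= tf$centers[K]) {
      k1[i] <- k2[i] <- K; a[i] <- 0
    } else {
      k <- findInterval(p, tf$centers)
      k1[i] <- k; k2[i] <- k + 1L
      a[i] <- (p - tf$centers[k]) / (tf$centers[k + 1] - tf$centers[k])
    }
  }
  list(k1 = k1, k2 = k2, a = a)
}

#' @export
apply_transform.pwa3d <- function(points, tf) {
  m <- if (is.matrix(points)) points else pts_mat(points)
  b <- pwa_blend(tf, m)
  out <- matrix(0, nrow(m), 3)
  for (i in seq_len(nrow(m))) {
    f1 <- tf$fits[[b$k1[i]]]
    f2 <- tf$fits[[b$k2[i]]]
    p1 <- as.numeric(f1$A %*% m[i, ] + f1$t)
    p2 <- as.numeric(f2$A %*% m[i, ] + f2$t)
    out[i, ] <- (1 - b$a[i]) * p1 + b$a[i] * p2
  }
  if (is.matrix(points)) out else set_pts(points, out)
}

# Pointwise (approximate Newton) inverse of a piecewise-affine map: finds x
# with f(x) = y, starting from `init`.  The Jacobian uses the blended affine
# and neglects the slowly varying blend-weight derivative.
invert_pwa <- function(tf, y, init) {
  x <- init
  for (iter in 1:12) {
    fx <- apply_transform(x, tf)
    r <- y - fx
    if (max(abs(r)) < 1e-9) break
    b <- pwa_blend(tf, x)
    for (i in seq_len(nrow(x))) {
      J <- (1 - b$a[i]) * tf$fits[[b$k1[i]]]$A + b$a[i] * tf$fits[[b$k2[i]]]$A
      step <- tryCatch(solve(J, r[i, ]), error = function(e) r[i, ] * 0)
      x[i, ] <- x[i, ] + step
    }
  }
  x
}

#' Shape context parameters
#'
#' A 3D shape context is a normalised histogram of neighbouring points in a
#' log-spherical binning around a cell: `R` radial shells log-spaced between
#' `r_min` and `r_max`, each divided into `F` angular sectors (`F/2` azimuthal
#' bins times 2 polar hemispheres; `F` must be even).
#'
#' @param R Number of radial shells.
#' @param F Number of angular sectors per shell (even).
#' @param r_min,r_max Radial range in voxels; neighbours beyond `r_max` are
#'   ignored, neighbours closer than `r_min` fall into the first shell.
#' @return A `shape_context_params` object.
#' @export
shape_context_params <- function(R = 5L, F = 12L, r_min = 2, r_max = 100) {
  if (R < 1 || F < 1) abort("R and F must be >= 1")
  if (F %% 2 != 0) abort("F must be even (azimuth x hemisphere sectors)")
  if (!(r_min > 0 && r_min < r_max)) abort("need 0 < r_min < r_max")
  structure(list(R = as.integer(R), F = as.integer(F),
                 r_min = r_min, r_max = r_max),
            class = "shape_context_params")
}

#' Deterministic PCA orientation frame of a point set
#'
#' Columns are the principal axes, sign-fixed so that each axis's largest
#' absolute loading is positive; used to pose-normalise shape-context sectors.
#'
#' @param points A `cell_points` tibble or n x 3 matrix.
#' @return A 3x3 rotation-like matrix (columns are axes).
#' @export
pca_frame <- function(points) {
  m <- if (is.matrix(points)) points else pts_mat(points)
  rot <- prcomp(m, center = TRUE)$rotation
  for (j in 1:3) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  rot
}

#' Shape context histogram of one cell
#'
#' Counts of the other points per (log-radial shell, angular sector) bin
#' around the point at `index`, normalised to sum 1.  Invariant to
#' translation; the angular sectors are computed in `frame` (default: the
#' point set's own PCA frame, making the histogram pose-normalised).
#'
#' @param points A `cell_points` tibble or n x 3 matrix.
#' @param index Row index of the focal cell.
#' @param params A [shape_context_params()].
#' @param frame Optional 3x3 orientation frame.
#' @return A numeric vector of length `R * F` (shell-major).
#' @export
shape_context <- function(points, index, params = shape_context_params(),
                          frame = NULL) {
  m <- if (is.matrix(points)) points else pts_mat(points)
  if (nrow(m) < 2) abort("shape context needs at least one other point")
  if (is.null(frame)) frame <- pca_frame(m)
  rel <- sweep(m[-index, , drop = FALSE], 2, m[index, ]) %*% frame
  sc_histogram(rel, params)
}

sc_histogram <- function(rel, params) {
  h <- numeric(params$R * params$F)
  r <- sqrt(rowSums(rel^2))
  keep <- r <= params$r_max & r > 0
  if (!any(keep)) {
    warn("all neighbours beyond r_max; zero shape context")
    return(h)
  }
  rel <- rel[keep, , drop = FALSE]
  r <- r[keep]
  lr <- log(pmax(r, params$r_min) / params$r_min)
  lmax <- log(params$r_max / params$r_min)
  shell <- pmin(params$R, floor(lr / lmax * params$R) + 1L)
  faz <- params$F %/% 2L
  phi <- atan2(rel[, 2], rel[, 1])
  azb <- pmin(faz, floor((phi + pi) / (2 * pi) * faz) + 1L)
  hemi <- ifelse(rel[, 3] >= 0, 1L, 2L)
  sector <- (hemi - 1L) * faz + azb
  bin <- (shell - 1L) * params$F + sector
  tab <- tabulate(bin, nbins = params$R * params$F)
  tab / sum(tab)
}

# shape contexts of all points, rows = cells
shape_context_all <- function(points, params = shape_context_params(),
                              frame = NULL) {
  m <- if (is.matrix(points)) points else pts_mat(points)
  if (is.null(frame)) frame <- pca_frame(m)
  t(vapply(seq_len(nrow(m)), function(i) {
    rel <- sweep(m[-i, , drop = FALSE], 2, m[i, ]) %*% frame
    sc_histogram(rel, params)
  }, numeric(params$R * params$F)))
}

#' Chi-square distance between two histograms
#'
#' `0.5 * sum (h1 - h2)^2 / (h1 + h2 + eps)`: symmetric, zero iff equal, and
#' equal to 1 for disjoint unit-mass histograms.
#'
#' @param h1,h2 Equal-length non-negative histograms.
#' @param eps Small stabiliser against empty bins.
#' @return A non-negative scalar.
#' @export
chi_square_dist <- function(h1, h2, eps = 1e-10) {
  if (length(h1) != length(h2)) abort("histograms must have equal length")
  0.5 * sum((h1 - h2)^2 / (h1 + h2 + eps))
}

# chi-square distances between all rows of H1 (n x B) and H2 (m x B)
chi_square_cross <- function(H1, H2, eps = 1e-10) {
  n <- nrow(H1); m <- nrow(H2)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    h2 <- H2[j, ]
    num <- sweep(H1, 2, h2)^2
    den <- sweep(H1, 2, h2, "+") + eps
    out[, j] <- 0.5 * rowSums(num / den)
  }
  out
}
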