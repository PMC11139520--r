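#' Phantom generator configuration
#'
#' Image phantoms of densely packed, blurred, ellipsoidal nuclei with
#' ground-truth instance masks.  Defaults emulate stacks of ~4-5 voxel-radius
#' nuclei with moderate blur and noise; with `min_sep` larger than twice the
#' maximum radius all cells are guaranteed disconnected.
#'
#' @param shape Volume shape `(nz, ny, nx)`.
#' @param n_cells Number of cells to place.
#' @param r_range Base semi-axis range in voxels; with the per-axis ellipsoid
#'   factors (0.85--1.18) the defaults keep every seed core (distance above
#'   the default watershed seed threshold) larger than the default minimum
#'   seed size.
#' @param min_sep Minimum centre-to-centre separation in voxels.
#' @param blur_sigma Gaussian blur of the rendered image.
#' @param noise_sigma Additive Gaussian noise level (intensity units).
#' @param intensity Per-cell peak intensity range.
#' @param seed Integer seed (full determinism).
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(shape = c(20L, 64L, 96L), n_cells = 12L,
                           r_range = c(4.2, 5), min_sep = 15,
                           blur_sigma = 1, noise_sigma = 0.05,
                           intensity = c(0.6, 1), seed = 1L) {
  if (min_sep < 0 || any(r_range <= 0)) abort("invalid phantom config")
  structure(list(shape = as.integer(shape), n_cells = as.integer(n_cells),
                 r_range = r_range, min_sep = min_sep,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 intensity = intensity, seed = as.integer(seed)),
            class = "phantom_config")
}

# uniform random proper rotation from QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a 3D phantom of blurred ellipsoidal cells
#'
#' Cell centres are rejection-sampled honouring `min_sep`; each cell is a
#' random-orientation ellipsoid (semi-axis ratios within a factor 2) painted
#' into the label mask, and an intensity blob of random amplitude in the
#' image.  The image is Gaussian-blurred, corrupted with additive noise, and
#' min-max scaled to `[0, 1]`.  Deterministic per seed.  If not all cells can
#' be placed within a bounded number of retries, fewer are returned with a
#' warning.
#'
#' @param cfg A [phantom_config()].
#' @return A list with `volume` (3D array), `mask` (instance mask) and
#'   `centers` (placed centres, `(x, y, z)`).
#' @export
make_phantom <- function(cfg = phantom_config()) {
  withr::with_seed(cfg$seed, {
    d <- cfg$shape
    rmax <- cfg$r_range[2] * sqrt(2)
    centers <- matrix(0, 0, 3)  # (z, y, x)
    tries <- 0L
    while (nrow(centers) < cfg$n_cells && tries < 2000L * max(cfg$n_cells, 1L)) {
      tries <- tries + 1L
      cand <- vapply(d, function(n) {
        if (n - rmax > 1 + rmax) runif(1, 1 + rmax, n - rmax) else (n + 1) / 2
      }, numeric(1))
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= cfg$min_sep) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < cfg$n_cells) {
      warn(sprintf("placed only %d of %d cells", nrow(centers), cfg$n_cells))
    }
    mask <- array(0L, d)
    img <- array(0, d)
    for (k in seq_len(nrow(centers))) {
      r0 <- runif(1, cfg$r_range[1], cfg$r_range[2])
      ax <- r0 * exp(runif(3, -0.165, 0.165))
      rot <- random_rotation()
      amp <- runif(1, cfg$intensity[1], cfg$intensity[2])
      ctr <- centers[k, ]
      rr <- ceiling(max(ax)) + 1L
      zr <- max(1L, floor(ctr[1] - rr)):min(d[1], ceiling(ctr[1] + rr))
      yr <- max(1L, floor(ctr[2] - rr)):min(d[2], ceiling(ctr[2] + rr))
      xr <- max(1L, floor(ctr[3] - rr)):min(d[3], ceiling(ctr[3] + rr))
      gg <- expand.grid(z = zr, y = yr, x = xr)
      rel <- cbind(gg$z - ctr[1], gg$y - ctr[2], gg$x - ctr[3]) %*% rot
      q <- (rel[, 1] / ax[1])^2 + (rel[, 2] / ax[2])^2 + (rel[, 3] / ax[3])^2
      lin <- gg$z + d[1] * ((gg$y - 1) + d[2] * (gg$x - 1))
      inside <- q <= 1
      mask[lin[inside]] <- k
      img[lin] <- img[lin] + amp * exp(-1.5 * q)
    }
    img <- gauss_blur3d(img, cfg$blur_sigma)
    img <- img + rnorm(length(img), sd = cfg$noise_sigma)
    img <- normalize_volume(img)
    list(volume = img, mask = as_instance_mask(mask),
         centers = grid_to_xyz(centers))
  })
}

#' Synthetic worm configuration
#'
#' Point-set generator emulating the stereotypic cell layout of an elongated
#' larva (by default 558 cells, matching the L1-stage whole-body cell count)
#' and its sample-to-sample variability: a bounded random affine pose, a
#' smooth sinusoidal axial bend, per-cell anisotropic Gaussian jitter with
#' cell-specific variability scales, and optional dropout.
#'
#' @param n_cells Number of cells `K`.
#' @param length,radius Tube dimensions in voxels (body axis along x).
#' @param n_samples Default number of training samples.
#' @param affine_sd Elementwise scale of the random affine perturbation.
#' @param rot_max Maximum random rotation angle (radians).
#' @param bend_amp Amplitude of the sinusoidal axial bend (voxels).
#' @param jitter_sigma Per-axis `(x, y, z)` jitter standard deviations.
#' @param heterogeneity Log-normal sdlog of per-cell variability scales
#'   (0 = homogeneous cells).
#' @param dropout Per-cell deletion probability.
#' @param min_sep Minimum inter-cell distance in the template.
#' @param seed Integer seed.
#' @return A `worm_config` object.
#' @export
worm_config <- function(n_cells = 558L, length = 300, radius = 14,
                        n_samples = 20L, affine_sd = 0.05, rot_max = 0.5,
                        bend_amp = 6, jitter_sigma = c(1.5, 1, 1),
                        heterogeneity = 0.5, dropout = 0, min_sep = 2.5,
                        seed = 1L) {
  if (n_cells < 4) abort("need at least 4 cells")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(list(n_cells = as.integer(n_cells), length = length,
                 radius = radius, n_samples = as.integer(n_samples),
                 affine_sd = affine_sd, rot_max = rot_max,
                 bend_amp = bend_amp,
                 jitter_sigma = rep_len(jitter_sigma, 3L),
                 heterogeneity = heterogeneity, dropout = dropout,
                 min_sep = min_sep, seed = as.integer(seed)),
            class = "worm_config")
}

#' Generate a synthetic atlas template point set
#'
#' `K` uniquely identified points inside a spindle-shaped tube (worm-like
#' elongated geometry, body axis along x with tapered ends), rejection
#' sampled to honour `min_sep`.  Each cell also receives a `var_scale`
#' column: a cell-specific variability multiplier (log-normal, controlled by
#' `heterogeneity`) that [make_synthetic_worm()] applies to its jitter --
#' emulating that some cells are biologically more variable than others.
#' Deterministic per `cfg$seed`.
#'
#' @param cfg A [worm_config()].
#' @return A `cell_points` tibble with ids `c000 ...` and a `var_scale`
#'   column.
#' @export
make_synthetic_atlas <- function(cfg = worm_config()) {
  withr::with_seed(cfg$seed, {
    pts <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pts) < cfg$n_cells && tries < 5000L * cfg$n_cells) {
      tries <- tries + 1L
      x <- runif(1, 0, cfg$length)
      taper <- sqrt(pmax(1 - (2 * x / cfg$length - 1)^2, 0.05))
      rloc <- cfg$radius * taper
      u <- runif(1)
      th <- runif(1, 0, 2 * pi)
      cand <- c(x, rloc * sqrt(u) * cos(th), rloc * sqrt(u) * sin(th))
      if (nrow(pts) == 0 ||
          min(sqrt(colSums((t(pts) - cand)^2))) >= cfg$min_sep) {
        pts <- rbind(pts, cand)
      }
    }
    if (nrow(pts) < cfg$n_cells) {
      warn(sprintf("placed only %d of %d template cells", nrow(pts), cfg$n_cells))
    }
    out <- cell_points(tibble(
      id = sprintf("c%03d", seq_len(nrow(pts)) - 1L),
      x = pts[, 1], y = pts[, 2], z = pts[, 3]
    ))
    out$var_scale <- exp(rnorm(nrow(out), 0, cfg$heterogeneity))
    out
  })
}

#' Deform a template into a synthetic individual
#'
#' Applies, in order: a smooth sinusoidal bend of the body axis, a bounded
#' random affine pose (rotation up to `rot_max`, elementwise perturbation
#' `affine_sd`, random translation), per-cell Gaussian jitter with per-axis
#' sigma `jitter_sigma` scaled by each cell's `var_scale`, and optional
#' dropout.  Ground-truth ids are carried along for surviving cells.
#'
#' @param atlas_points A template from [make_synthetic_atlas()].
#' @param cfg A [worm_config()].
#' @param seed Seed for this individual (distinct individuals from one
#'   template).
#' @return A `cell_points` tibble with true `id`s.
#' @export
make_synthetic_worm <- function(atlas_points, cfg = worm_config(), seed = 1L) {
  withr::with_seed(seed, {
    ps <- cell_points(atlas_points)
    m <- pts_mat(ps)
    # Smooth random body deformation in the template frame (axis = x): a few
    # low-frequency harmonics with random amplitude and phase per sample.
    # Inter-individual variability in an elongated animal is dominated by
    # such coherent posture/tissue deformation, which displaces cells while
    # preserving their local neighbourhood structure; the iid jitter below
    # adds the residual per-cell scatter on top.
    for (ax in 2:3) {
      for (k in 1:3) {
        amp <- (cfg$bend_amp / k) * runif(1, 0.3, 1)
        phase <- runif(1, 0, 2 * pi)
        m[, ax] <- m[, ax] + amp * sin(2 * pi * k * m[, 1] / cfg$length + phase)
      }
    }
    # mild axial compression/stretch wave
    m[, 1] <- m[, 1] + (cfg$bend_amp / 3) * runif(1, 0.3, 1) *
      sin(2 * pi * m[, 1] / cfg$length + runif(1, 0, 2 * pi))
    # per-cell anisotropic jitter, in the body frame (anatomical variability
    # is defined relative to the animal, not the imaging pose)
    vs <- if ("var_scale" %in% names(ps)) ps$var_scale else rep(1, nrow(ps))
    for (ax in 1:3) {
      m[, ax] <- m[, ax] + rnorm(nrow(m), 0, cfg$jitter_sigma[ax]) * vs
    }
    # bounded random affine pose
    ang <- runif(1, 0, cfg$rot_max)
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    rot <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    A <- rot %*% (diag(3) + matrix(rnorm(9, sd = cfg$affine_sd), 3, 3))
    tr <- runif(3, -1, 1) * cfg$affine_sd * cfg$length
    m <- sweep(m %*% t(A), 2, tr, "+")
    out <- set_pts(ps, m)
    if (cfg$dropout > 0) {
      keep <- runif(nrow(out)) >= cfg$dropout
      if (sum(keep) < 4) abort("dropout left fewer than 4 cells")
      out <- out[keep, ]
    }
    cell_points(out)
  })
}
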