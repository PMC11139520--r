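#' Atlas construction configuration
#'
#' @param tol_factor Convergence tolerance for the average-position iteration,
#'   as a fraction of the body length (largest coordinate extent).
#' @param max_iter Maximum alignment iterations.
#' @param n_segments,overlap Piecewise-affine settings ([fit_pwa()]).
#' @param sc_params Shape-context binning ([shape_context_params()]).
#' @return An `atlas_config` object.
#' @export
atlas_config <- function(tol_factor = 1e-3, max_iter = 20L, n_segments = 8L,
                         overlap = 0.2, sc_params = shape_context_params()) {
  structure(list(tol_factor = tol_factor, max_iter = as.integer(max_iter),
                 n_segments = as.integer(n_segments), overlap = overlap,
                 sc_params = sc_params),
            class = "atlas_config")
}

#' Average spatial positions (ASP) of identified cells across samples
#'
#' Starting from the first sample as the initial template, every sample is
#' affine-aligned to the current template and the template is moved by the
#' per-cell mean displacement of the aligned samples.  Iterating re-fits the
#' affines against the updated template, so the procedure converges to the
#' fixed point at which the average residual deformation of the aligned
#' samples is zero -- removing the shape bias toward the arbitrarily chosen
#' initial sample.  Finally each sample is mapped to the converged template
#' with a piecewise-affine transform and the mapped positions are averaged
#' into the final ASP.
#'
#' Cells missing from a sample are simply skipped in that sample's averages
#' (masked mean).  The ASP is only defined up to a global affine
#' transformation (the gauge is set by the initial sample).
#'
#' @param samples A list of `cell_points` tibbles sharing identity labels.
#' @param cfg An [atlas_config()].
#' @return A list with `asp` (a `cell_points` tibble), `aligned` (the
#'   PWA-mapped samples), `iterations`, `converged`, `movement`.
#' @export
build_asp <- function(samples, cfg = atlas_config()) {
  if (length(samples) < 2) abort("at least 2 samples are required")
  samples <- lapply(samples, cell_points)
  ids <- sort(unique(unlist(lapply(samples, function(s) s$id))))
  if (any(is.na(ids))) abort("atlas samples must have complete ids")
  asp <- matrix(NA_real_, length(ids), 3, dimnames = list(ids, c("x", "y", "z")))
  m1 <- pts_mat(samples[[1]])
  asp[samples[[1]]$id, ] <- m1
  # seed cells absent from sample 1 from the first sample containing them
  for (s in samples[-1]) {
    missing <- ids[is.na(asp[, 1])]
    if (length(missing) == 0) break
    hit <- intersect(missing, s$id)
    asp[hit, ] <- pts_mat(s)[match(hit, s$id), , drop = FALSE]
  }
  body_len <- max(apply(asp, 2, function(v) diff(range(v, na.rm = TRUE))))
  tol <- cfg$tol_factor * body_len
  movement <- Inf
  it <- 0L
  aligned_mats <- NULL
  while (it < cfg$max_iter && movement >= tol) {
    it <- it + 1L
    acc <- asp * 0
    cnt <- numeric(length(ids))
    Abar <- matrix(0, 3, 3)
    tbar <- numeric(3)
    for (s in samples) {
      rows <- match(s$id, ids)
      tf <- fit_affine(pts_mat(s), asp[rows, , drop = FALSE])
      al <- apply_transform(pts_mat(s), tf)
      acc[rows, ] <- acc[rows, ] + al
      cnt[rows] <- cnt[rows] + 1
      Abar <- Abar + tf$A / length(samples)
      tbar <- tbar + tf$t / length(samples)
    }
    newasp <- acc / cnt
    # undo the average sample-to-template deformation: an errors-in-variables
    # affine fit systematically contracts the template, and without this
    # inversion the iteration collapses the short body axes
    newasp <- t(solve(Abar, t(newasp) - tbar))
    movement <- max(sqrt(rowSums((newasp - asp)^2)))
    asp <- newasp
  }
  # Final pass: piecewise-affine map every sample onto the converged
  # template.  The PWA is fitted in the template-to-sample direction (clean
  # predictor coordinates) and inverted pointwise: fitting on the noisy
  # sample coordinates would attenuate the very positional variability the
  # SPV is supposed to measure.
  aligned <- lapply(samples, function(s) {
    rows <- match(s$id, ids)
    tf <- fit_pwa(asp[rows, , drop = FALSE], pts_mat(s),
                  n_segments = cfg$n_segments, overlap = cfg$overlap)
    set_pts(s, invert_pwa(tf, pts_mat(s), init = asp[rows, , drop = FALSE]))
  })
  acc <- asp * 0
  cnt <- numeric(length(ids))
  for (s in aligned) {
    rows <- match(s$id, ids)
    acc[rows, ] <- acc[rows, ] + pts_mat(s)
    cnt[rows] <- cnt[rows] + 1
  }
  asp <- acc / cnt
  if (movement >= tol) {
    warn(sprintf("ASP iteration did not converge (movement %.3g >= tol %.3g)",
                 movement, tol))
  }
  list(
    asp = cell_points(tibble(id = ids, x = asp[, 1], y = asp[, 2], z = asp[, 3])),
    aligned = aligned,
    iterations = it,
    converged = movement < tol,
    movement = movement
  )
}

#' Spatial position variation (SPV)
#'
#' Per-cell, per-axis standard deviation of the PWA-aligned sample positions.
#' Cells present in fewer than 2 samples get the global median sigma (with a
#' warning).
#'
#' @param asp The ASP `cell_points` (defines the cell order).
#' @param aligned The PWA-aligned samples from [build_asp()].
#' @return A tibble with columns `id`, `sx`, `sy`, `sz`.
#' @export
build_spv <- function(asp, aligned) {
  ids <- asp$id
  out <- matrix(NA_real_, length(ids), 3)
  for (j in seq_along(ids)) {
    pos <- do.call(rbind, lapply(aligned, function(s) {
      k <- match(ids[j], s$id)
      if (is.na(k)) NULL else pts_mat(s)[k, , drop = FALSE]
    }))
    if (!is.null(pos) && nrow(pos) >= 2) out[j, ] <- apply(pos, 2, sd)
  }
  if (anyNA(out)) {
    warn("cells present in < 2 samples: sigma set to the global median")
    med <- apply(out, 2, median, na.rm = TRUE)
    for (ax in 1:3) out[is.na(out[, ax]), ax] <- med[ax]
  }
  tibble(id = ids, sx = out[, 1], sy = out[, 2], sz = out[, 3])
}

#' Topological structure variation (TSV)
#'
#' For every atlas cell, the mean chi-square distance between its shape
#' context in the ASP and the shape contexts of the corresponding cell in the
#' PWA-aligned samples.  Identical samples give zero; larger positional
#' scatter of neighbourhoods gives larger values.
#'
#' @inheritParams build_spv
#' @param sc_params A [shape_context_params()].
#' @return A list with `gamma` (tibble `id`, `gamma`) and `sc_ref` (matrix of
#'   ASP shape contexts, rows in `asp` order).
#' @export
build_tsv <- function(asp, aligned, sc_params = shape_context_params()) {
  ids <- asp$id
  frame <- pca_frame(asp)
  sc_ref <- shape_context_all(asp, sc_params, frame = frame)
  acc <- numeric(length(ids))
  cnt <- numeric(length(ids))
  for (s in aligned) {
    scs <- shape_context_all(s, sc_params, frame = pca_frame(s))
    rows <- match(s$id, ids)
    for (k in seq_along(rows)) {
      j <- rows[k]
      acc[j] <- acc[j] + chi_square_dist(sc_ref[j, ], scs[k, ])
      cnt[j] <- cnt[j] + 1
    }
  }
  gamma <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  if (anyNA(gamma)) {
    warn("cells absent from all samples: gamma set to the global median")
    gamma[is.na(gamma)] <- median(gamma, na.rm = TRUE)
  }
  list(gamma = tibble(id = ids, gamma = gamma), sc_ref = sc_ref)
}

#' Build the full three-part statistical atlas
#'
#' Combines [build_asp()], [build_spv()] and [build_tsv()] into a
#' `cell_atlas`: per-cell average positions, per-axis positional standard
#' deviations, shape-context variability, and the reference shape contexts
#' used during recognition.
#'
#' @inheritParams build_asp
#' @return A `cell_atlas` object (a tibble with columns `id, x, y, z, sx, sy,
#'   sz, gamma` plus attributes `sc_ref`, `sc_params`, `frame`, `build`).
#' @export
build_atlas <- function(samples, cfg = atlas_config()) {
  ba <- build_asp(samples, cfg)
  spv <- build_spv(ba$asp, ba$aligned)
  tsv <- build_tsv(ba$asp, ba$aligned, cfg$sc_params)
  at <- ba$asp
  at$sx <- spv$sx; at$sy <- spv$sy; at$sz <- spv$sz
  at$gamma <- tsv$gamma$gamma
  attr(at, "sc_ref") <- tsv$sc_ref
  attr(at, "sc_params") <- cfg$sc_params
  attr(at, "frame") <- pca_frame(at)
  attr(at, "build") <- list(iterations = ba$iterations,
                            converged = ba$converged,
                            n_samples = length(samples))
  class(at) <- c("cell_atlas", class(at))
  at
}

#' @export
print.cell_atlas <- function(x, ...) {
  b <- attr(x, "build")
  cat(sprintf("<cell_atlas> %d cells (from %d samples, %d iterations%s)\n",
              nrow(x), b$n_samples, b$iterations,
              if (b$converged) ", converged" else ", NOT converged"))
  NextMethod()
}

#' @export
tidy.cell_atlas <- function(x, ...) {
  as_tibble(x[, c("id", "x", "y", "z", "sx", "sy", "sz", "gamma")])
}

#' @export
glance.cell_atlas <- function(x, ...) {
  b <- attr(x, "build")
  tibble(n_cells = nrow(x), n_samples = b$n_samples,
         iterations = b$iterations, converged = b$converged,
         mean_sigma = mean(c(x$sx, x$sy, x$sz)), mean_gamma = mean(x$gamma))
}
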