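# Independent oracles and shared fixtures, all generated in code.

# brute-force nearest-background displacement with the z-major lexicographic
# tie-break, by exhaustive search over all background voxels
brute_force_dvf <- function(mask) {
  d <- dim(mask)
  bg <- which(mask == 0, arr.ind = TRUE)  # cols: z, y, x (dim1, dim2, dim3)
  ord <- order(bg[, 1], bg[, 2], bg[, 3])
  bg <- bg[ord, , drop = FALSE]
  dx <- dy <- dz <- array(0, d)
  fg <- which(mask > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    v <- fg[r, ]
    d2 <- (bg[, 1] - v[1])^2 + (bg[, 2] - v[2])^2 + (bg[, 3] - v[3])^2
    best <- which(d2 == min(d2))[1]  # bg is in z-major order already
    dz[v[1], v[2], v[3]] <- v[1] - bg[best, 1]
    dy[v[1], v[2], v[3]] <- v[2] - bg[best, 2]
    dx[v[1], v[2], v[3]] <- v[3] - bg[best, 3]
  }
  as_dvf(dx, dy, dz)
}

brute_force_edt <- function(mask) {
  d <- dim(mask)
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- array(0, d)
  fg <- which(mask > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    v <- fg[r, ]
    out[v[1], v[2], v[3]] <-
      sqrt(min((bg[, 1] - v[1])^2 + (bg[, 2] - v[2])^2 + (bg[, 3] - v[3])^2))
  }
  out
}

# exhaustive minimum-cost assignment over all permutations (square) or
# injections (rectangular with nrow <= ncol)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, m <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    cst <- sum(cost[cbind(seq_len(n), sel)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- sel
    }
  }
  list(assignment = best, cost = best_cost)
}

# small labelled mask of two separated spheres (radius 4, centres 18 apart)
two_sphere_mask <- function(r = 4, sep = 18, pad = 10) {
  d <- c(2 * pad + 1, 2 * pad + 1, sep + 2 * pad + 1)
  mk <- array(0L, d)
  c1 <- c(pad + 1, pad + 1, pad + 1)
  c2 <- c(pad + 1, pad + 1, pad + 1 + sep)
  gg <- which(mk == 0, arr.ind = TRUE)
  d1 <- (gg[, 1] - c1[1])^2 + (gg[, 2] - c1[2])^2 + (gg[, 3] - c1[3])^2
  d2 <- (gg[, 1] - c2[1])^2 + (gg[, 2] - c2[2])^2 + (gg[, 3] - c2[3])^2
  mk[gg[d1 <= r^2, , drop = FALSE]] <- 1L
  mk[gg[d2 <= r^2, , drop = FALSE]] <- 2L
  mk
}

# tiny random labelled mask for property tests
random_mask <- function(dims = c(6, 7, 8), p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    mk <- array(as.integer(runif(prod(dims)) < p), dims)
    mk[1, 1, 1] <- 0L
    mk
  })
}

# Shared recognition fixture: a K-cell template, its median NN distance, and
# an atlas built from training worms drawn at `jitter_frac` of that distance
# (train and test individuals come from the same population, as in any real
# atlas study).
recognition_fixture <- function(K = 100, n_train = 15, seed = 5,
                                jitter_frac = NULL) {
  cfg <- worm_config(n_cells = K, seed = seed)
  tmpl <- make_synthetic_atlas(cfg)
  mednn <- median(apply(as.matrix(dist(tmpl[, c("x", "y", "z")])), 1,
                        function(r) min(r[r > 0])))
  if (!is.null(jitter_frac)) {
    cfg <- worm_config(n_cells = K, seed = seed,
                       jitter_sigma = rep(jitter_frac * mednn, 3))
  }
  samples <- lapply(seq_len(n_train),
                    function(s) make_synthetic_worm(tmpl, cfg, seed = 100 + s))
  atlas <- suppressWarnings(build_atlas(samples))
  list(cfg = cfg, template = tmpl, atlas = atlas, mednn = mednn)
}
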