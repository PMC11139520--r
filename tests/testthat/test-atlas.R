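rand_points <- function(n, seed = 1, scale = 50) {
  withr::with_seed(seed, {
    cell_points(tibble::tibble(
      id = sprintf("c%03d", seq_len(n)),
      x = runif(n, 0, 4 * scale), y = runif(n, 0, scale), z = runif(n, 0, scale)
    ))
  })
}

test_that("affine fitting recovers exact and noisy transforms", {
  ps <- rand_points(30, seed = 1)
  # identity correspondence
  tf <- fit_affine(ps, ps)
  expect_equal(tf$A, diag(3), tolerance = 1e-9)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-8)
  # exact recovery of a known affine
  A <- matrix(c(1.2, 0.1, 0, -0.2, 0.9, 0.05, 0, 0.1, 1.1), 3, 3)
  tr <- c(5, -3, 2)
  dst <- ps
  m <- as.matrix(ps[, c("x", "y", "z")])
  dst[, c("x", "y", "z")] <- sweep(m %*% t(A), 2, tr, "+")
  tf2 <- fit_affine(ps, dst)
  expect_equal(tf2$A, A, tolerance = 1e-6)
  expect_equal(tf2$t, tr, tolerance = 1e-6)
  # noisy fit equals the closed-form normal-equation solution
  withr::with_seed(2, noisy <- as.matrix(dst[, c("x", "y", "z")]) +
                     matrix(rnorm(90), ncol = 3))
  tf3 <- fit_affine(m, noisy, correspondences = cbind(1:30, 1:30))
  X <- cbind(m, 1)
  B <- unname(solve(t(X) %*% X, t(X) %*% noisy))
  expect_equal(tf3$A, t(B[1:3, ]), tolerance = 1e-8)
  expect_error(fit_affine(m[1:3, ], noisy[1:3, ],
                          correspondences = cbind(1:3, 1:3)), "4")
})

test_that("piecewise affine reduces to global affine and beats it when bent", {
  ps <- rand_points(80, seed = 3)
  m <- as.matrix(ps[, c("x", "y", "z")])
  A <- diag(c(1.1, 0.9, 1.05))
  dst <- sweep(m %*% t(A), 2, c(1, 2, 3), "+")
  # n_segments = 1 is identical to the global affine
  pwa1 <- fit_pwa(m, dst, correspondences = cbind(1:80, 1:80), n_segments = 1)
  expect_equal(apply_transform(m, pwa1), dst, tolerance = 1e-6)
  # globally affine data: every segment recovers the same map
  pwa4 <- fit_pwa(m, dst, correspondences = cbind(1:80, 1:80), n_segments = 4)
  expect_equal(apply_transform(m, pwa4), dst, tolerance = 1e-6)
  # sinusoidally bent target: PWA residual < affine residual
  bent <- dst
  bent[, 2] <- bent[, 2] + 10 * sin(2 * pi * m[, 1] / 200)
  aff <- fit_affine(m, bent, correspondences = cbind(1:80, 1:80))
  r_aff <- sum((apply_transform(m, aff) - bent)^2)
  pwa <- fit_pwa(m, bent, correspondences = cbind(1:80, 1:80), n_segments = 6)
  r_pwa <- sum((apply_transform(m, pwa) - bent)^2)
  expect_lt(r_pwa, r_aff)
})

test_that("pointwise PWA inversion solves f(x) = y", {
  ps <- rand_points(60, seed = 4)
  m <- as.matrix(ps[, c("x", "y", "z")])
  bent <- m
  bent[, 2] <- bent[, 2] + 8 * sin(2 * pi * m[, 1] / 180)
  tf <- fit_pwa(m, bent, correspondences = cbind(1:60, 1:60), n_segments = 6)
  y <- apply_transform(m, tf)
  x <- cellasr:::invert_pwa(tf, y, init = m + 1)
  expect_equal(apply_transform(x, tf), y, tolerance = 1e-6)
})

test_that("shape context bins a single neighbour where the geometry says", {
  p <- shape_context_params(R = 5, F = 12, r_min = 2, r_max = 100)
  r <- 2 * (100 / 2)^(0.5 / 5)  # middle of the first log shell
  pts <- rbind(c(0, 0, 0), c(r, 0, 0))
  h <- shape_context(pts, 1, p, frame = diag(3))
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 1L)
  # shell 1, azimuth bin for phi = 0 (of 6), upper hemisphere
  azbin <- floor((0 + pi) / (2 * pi) * 6) + 1
  expect_equal(which(h > 0), (1 - 1) * 12 + azbin)
})

test_that("shape context is translation invariant and count-normalised", {
  withr::with_seed(6, pts <- matrix(runif(60, 0, 40), ncol = 3))
  p <- shape_context_params()
  h1 <- shape_context(pts, 3, p, frame = diag(3))
  h2 <- shape_context(sweep(pts, 2, c(11, -7, 3), "+"), 3, p, frame = diag(3))
  expect_equal(h1, h2)
  # duplicating every point leaves the normalised histogram unchanged
  rel <- sweep(pts[-3, ], 2, pts[3, ])
  h3 <- cellasr:::sc_histogram(rbind(rel, rel), p)
  expect_equal(h3, h1)
  # all neighbours beyond r_max: zero histogram with a warning
  far <- rbind(c(0, 0, 0), c(500, 0, 0))
  expect_warning(h4 <- shape_context(far, 1, p, frame = diag(3)), "r_max")
  expect_true(all(h4 == 0))
})

test_that("chi-square distance is a symmetric divergence", {
  h1 <- c(1, 0, 0, 0)
  h2 <- c(0, 1, 0, 0)
  expect_equal(chi_square_dist(h1, h1), 0)
  expect_equal(chi_square_dist(h1, h2), 1, tolerance = 1e-6)
  withr::with_seed(7, {
    a <- runif(10); a <- a / sum(a)
    b <- runif(10); b <- b / sum(b)
  })
  expect_equal(chi_square_dist(a, b), chi_square_dist(b, a))
  expect_error(chi_square_dist(a, b[1:5]), "length")
})

test_that("identical samples give a degenerate atlas: ASP = sample, SPV = 0, TSV = 0", {
  tmpl <- make_synthetic_atlas(worm_config(n_cells = 60, seed = 2))
  samples <- lapply(1:4, function(i) tmpl)
  ba <- build_asp(samples, atlas_config())
  expect_true(ba$converged)
  expect_equal(as.matrix(ba$asp[, c("x", "y", "z")]),
               as.matrix(tmpl[, c("x", "y", "z")]), tolerance = 1e-6,
               ignore_attr = TRUE)
  spv <- build_spv(ba$asp, ba$aligned)
  expect_equal(max(c(spv$sx, spv$sy, spv$sz)), 0, tolerance = 1e-6)
  tsv <- build_tsv(ba$asp, ba$aligned, shape_context_params())
  expect_equal(max(tsv$gamma$gamma), 0, tolerance = 1e-8)
})

test_that("ASP recovery is invariant to sample ordering (up to affine)", {
  cfg <- worm_config(n_cells = 80, seed = 3, jitter_sigma = c(0.5, 0.5, 0.5),
                     heterogeneity = 0)
  tmpl <- make_synthetic_atlas(cfg)
  samples <- lapply(1:6, function(s) make_synthetic_worm(tmpl, cfg, seed = 40 + s))
  a1 <- build_asp(samples, atlas_config())$asp
  a2 <- build_asp(rev(samples), atlas_config())$asp
  tf <- fit_affine(a2, a1)
  aligned <- apply_transform(a2, tf)
  res <- sqrt(mean(rowSums((as.matrix(aligned[, c("x", "y", "z")]) -
                              as.matrix(a1[, c("x", "y", "z")]))^2)))
  expect_lt(res, 0.5)  # within the jitter scale
})

test_that("a missing cell is tolerated via masked averaging", {
  cfg <- worm_config(n_cells = 40, seed = 8, jitter_sigma = c(0.2, 0.2, 0.2),
                     heterogeneity = 0)
  tmpl <- make_synthetic_atlas(cfg)
  samples <- lapply(1:5, function(s) make_synthetic_worm(tmpl, cfg, seed = 60 + s))
  samples[[2]] <- samples[[2]][-7, ]  # drop one cell from one sample
  ba <- build_asp(samples, atlas_config(n_segments = 4))
  expect_equal(nrow(ba$asp), 40L)
  spv <- build_spv(ba$asp, ba$aligned)
  expect_true(all(is.finite(spv$sx)))
})
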