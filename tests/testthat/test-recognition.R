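test_that("centroids equal the brute-force per-label coordinate mean", {
  mk <- array(0L, c(9, 9, 9))
  mk[4:6, 4:6, 4:6] <- 1L  # cube centred at (5,5,5)
  mk[1:2, 1:2, 1:2] <- 2L
  cp <- extract_centroids(mk)
  expect_equal(nrow(cp), 2L)
  expect_equal(unlist(cp[cp$label == 1, c("x", "y", "z")], use.names = FALSE),
               c(5, 5, 5))
  # naive loop oracle for label 2
  w <- which(mk == 2L, arr.ind = TRUE)
  expect_equal(unlist(cp[cp$label == 2, c("x", "y", "z")], use.names = FALSE),
               c(mean(w[, 3]), mean(w[, 2]), mean(w[, 1])))
  expect_error(extract_centroids(array(0L, c(3, 3, 3))), "no instances")
})

test_that("PCA alignment undoes rotation and per-axis scale", {
  tmpl <- make_synthetic_atlas(worm_config(n_cells = 60, seed = 4))
  m <- as.matrix(tmpl[, c("x", "y", "z")])
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(m %*% t(1.4 * R), 2, c(10, -5, 3), "+")
  tf <- pca_align(moved, m)
  back <- apply_transform(moved, tf)
  expect_equal(back, m, tolerance = 1e-6)
  # self-alignment is (numerically) the identity map
  tf0 <- pca_align(m, m)
  expect_equal(apply_transform(m, tf0), m, tolerance = 1e-6)
  # proper rotations only: the fitted map never reflects
  expect_gt(det(tf$A), 0)
  expect_error(pca_align(m[1:3, ], m), "4 points")
})

test_that("assignment solver equals exhaustive enumeration", {
  withr::with_seed(31, {
    for (trial in 1:25) {
      n <- sample(2:7, 1)
      m <- n + sample(0:1, 1)
      cost <- matrix(runif(n * m), n, m)
      got <- solve_assignment(cost)
      oracle <- brute_force_assignment(cost)
      expect_equal(sum(cost[cbind(got$subject, got$target)]), oracle$cost,
                   tolerance = 1e-12)
    }
  })
})

test_that("prior similarity kernels follow their closed forms", {
  expect_equal(spv_similarity(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(tsv_similarity(0, 0.5), 1)
  # displacement of one sigma per axis at omega 1: exp(-3/2)
  expect_equal(spv_similarity(c(2, 3, 4), c(1, 2, 3), c(1, 1, 1)),
               exp(-3 / 2))
  expect_equal(tsv_similarity(0.2, 0.1), exp(-(0.2^2 / 0.1^2) / 2))
  expect_warning(spv_similarity(c(0, 0, 0), c(0, 0, 0), c(0, 1, 1)),
                 "floored")
})

test_that("RPM recovers the identity correspondence on a clean copy", {
  tmpl <- make_synthetic_atlas(worm_config(n_cells = 40, seed = 6))
  m <- as.matrix(tmpl[, c("x", "y", "z")])
  ms <- rpm_match(m, m, recognition_config(), shape_context_params())
  expect_equal(ms$correspondences$target, seq_len(40))
})

test_that("disabling the shape term reduces RPM to pure spatial matching", {
  tmpl <- make_synthetic_atlas(worm_config(n_cells = 10, seed = 7,
                                           length = 80, radius = 8))
  m <- as.matrix(tmpl[, c("x", "y", "z")])
  withr::with_seed(3, noisy <- m + matrix(rnorm(30, sd = 0.3), ncol = 3))
  # beta0 = Inf removes the shape-context term exactly; an astronomically
  # large finite beta0 must do the same, and the pure spatial match recovers
  # the identity correspondence on this 10-point instance
  spatial <- rpm_match(noisy, m, recognition_config(beta0 = Inf),
                       shape_context_params())
  huge <- rpm_match(noisy, m, recognition_config(beta0 = 1e12),
                    shape_context_params())
  expect_equal(spatial$correspondences, huge$correspondences,
               tolerance = 1e-8)
  expect_equal(spatial$correspondences$target, 1:10)
})

test_that("RPM hard matching equals the assignment oracle on a small set", {
  tmpl <- make_synthetic_atlas(worm_config(n_cells = 8, seed = 8,
                                           length = 60, radius = 6))
  m <- as.matrix(tmpl[, c("x", "y", "z")])
  withr::with_seed(4, {
    perm <- sample(8)
    noisy <- m[perm, ] + matrix(rnorm(24, sd = 0.2), ncol = 3)
  })
  ms <- rpm_match(noisy, m, recognition_config(beta0 = Inf),
                  shape_context_params())
  # oracle on the final RPM cost (pure spatial): the returned hard matching
  # must be the minimum-cost assignment of the mapped subject to the target
  S <- apply_transform(noisy, ms$transform)
  d <- as.matrix(stats::dist(rbind(S, m)))[1:8, 9:16]
  oracle <- brute_force_assignment(d / max(ms$alpha, 0.1))
  expect_equal(ms$correspondences$target, oracle$assignment)
})

test_that("map_subject follows affine plus piecewise refinement", {
  tmpl <- make_synthetic_atlas(worm_config(n_cells = 70, seed = 9))
  m <- as.matrix(tmpl[, c("x", "y", "z")])
  A <- diag(c(1.2, 0.9, 1.1))
  moved <- sweep(m %*% t(A), 2, c(4, 4, 4), "+")
  mapped <- map_subject(moved, cbind(1:70, 1:70), m, n_segments = 4)
  expect_equal(mapped, m, tolerance = 1e-5, ignore_attr = TRUE)
  # bent subject: adding the piecewise step beats affine alone
  bent <- moved
  bent[, 2] <- bent[, 2] + 6 * sin(2 * pi * m[, 1] / 150)
  aff <- fit_affine(bent, m, correspondences = cbind(1:70, 1:70))
  r_aff <- sum((apply_transform(bent, aff) - m)^2)
  r_map <- sum((map_subject(bent, cbind(1:70, 1:70), m, n_segments = 6) - m)^2)
  expect_lt(r_map, r_aff)
  expect_error(map_subject(moved, cbind(integer(0), integer(0)), m), "empty")
})

test_that("consensus refinement keeps only agreeing pairs", {
  fx <- recognition_fixture(K = 40, n_train = 8, seed = 12)
  atlas <- fx$atlas
  sub <- as.matrix(atlas[, c("x", "y", "z")])
  cfg <- recognition_config()
  cons <- refine_bipartite(sub, atlas, cfg)
  # on the ASP itself both priors agree everywhere
  expect_equal(cons$target, cons$subject)
  expect_equal(nrow(cons), nrow(atlas))
  # position-prior only: full assignment is returned
  cfg2 <- recognition_config(priors = "spv")
  expect_equal(nrow(refine_bipartite(sub, atlas, cfg2)), nrow(atlas))
})

test_that("hard matchings of the full pipeline are injective", {
  fx <- recognition_fixture(K = 50, n_train = 8, seed = 13)
  wcfg <- worm_config(n_cells = 50, seed = 13,
                      jitter_sigma = rep(0.15 * fx$mednn, 3))
  worm <- make_synthetic_worm(fx$template, wcfg, seed = 991)
  res <- suppressWarnings(recognize(worm, fx$atlas))
  ids <- res$id[!is.na(res$id)]
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(nrow(res), nrow(worm))
})

test_that("the ASP recognises itself perfectly", {
  fx <- recognition_fixture(K = 60, n_train = 8, seed = 14)
  sub <- cell_points(tibble::tibble(id = NA_character_, x = fx$atlas$x,
                                    y = fx$atlas$y, z = fx$atlas$z))
  res <- suppressWarnings(recognize(sub, fx$atlas))
  expect_equal(recognition_accuracy(res, fx$atlas$id), 1)
  expect_true(all(res$confidence[!is.na(res$confidence)] > 0))
})
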