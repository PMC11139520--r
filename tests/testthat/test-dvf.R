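test_that("DVF of trivial masks matches the definition", {
  # all background
  z <- array(0L, c(4, 4, 4))
  f <- compute_dvf(z)
  expect_true(all(f$dx == 0) && all(f$dy == 0) && all(f$dz == 0))

  # single foreground voxel: unit vector to a face neighbour, tie broken to
  # the smallest z-major linear index (the z-1 neighbour)
  m <- array(0L, c(5, 5, 5))
  m[3, 3, 3] <- 1L
  f <- compute_dvf(m)
  expect_equal(c(f$dx[3, 3, 3], f$dy[3, 3, 3], f$dz[3, 3, 3]), c(0, 0, 1))
  expect_equal(dvf_to_distance(f)[3, 3, 3], 1)

  # 1x1x7 line: displacements to the nearer end, centre tie to the lower x
  lm <- array(c(0L, 1L, 1L, 1L, 1L, 1L, 0L), c(1, 1, 7))
  f <- compute_dvf(lm)
  expect_equal(as.vector(f$dx), c(0, 1, 2, 3, -2, -1, 0))
  expect_true(all(f$dy == 0) && all(f$dz == 0))
})

test_that("DVF equals the brute-force nearest-background oracle, with ties", {
  for (seed in 1:6) {
    mk <- random_mask(seed = seed)
    f <- compute_dvf(mk)
    o <- brute_force_dvf(mk)
    expect_equal(f$dx, o$dx)
    expect_equal(f$dy, o$dy)
    expect_equal(f$dz, o$dz)
  }
})

test_that("distance map equals an independent EDT and pointers are valid", {
  for (seed in 1:4) {
    mk <- random_mask(dims = c(7, 9, 8), seed = seed)
    f <- compute_dvf(mk)
    dm <- dvf_to_distance(f)
    expect_equal(dm, brute_force_edt(mk))
    # subtracting the vector from each foreground voxel lands on background
    fg <- which(mk > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(fg))) {
      v <- fg[r, ]
      tgt <- c(v[1] - f$dz[v[1], v[2], v[3]],
               v[2] - f$dy[v[1], v[2], v[3]],
               v[3] - f$dx[v[1], v[2], v[3]])
      expect_equal(mk[tgt[1], tgt[2], tgt[3]], 0L)
    }
  }
})

test_that("DVF is equivariant under integer translation away from borders", {
  mk <- array(0L, c(9, 9, 9))
  mk[3:5, 3:5, 3:5] <- 1L
  mk2 <- array(0L, c(9, 9, 9))
  mk2[4:6, 5:7, 4:6] <- 1L
  f1 <- compute_dvf(mk)
  f2 <- compute_dvf(mk2)
  expect_equal(f1$dx[3:5, 3:5, 3:5], f2$dx[4:6, 5:7, 4:6])
  expect_equal(f1$dy[3:5, 3:5, 3:5], f2$dy[4:6, 5:7, 4:6])
  expect_equal(f1$dz[3:5, 3:5, 3:5], f2$dz[4:6, 5:7, 4:6])
})

test_that("anisotropic spacing changes the chosen nearest background", {
  # a voxel 2 steps from background in z and 3 in x: with z-spacing 2 the
  # x-direction (distance 3) beats the z-direction (distance 4)
  mk <- array(1L, c(7, 7, 9))
  mk[1, , ] <- 0L  # background plane at z = 1
  mk[, , 1] <- 0L  # and at x = 1
  f1 <- compute_dvf(mk)
  expect_equal(f1$dz[3, 4, 5], 2)  # isotropic: z plane is closer
  f2 <- compute_dvf(mk, spacing = c(2, 1, 1))
  expect_equal(f2$dx[3, 4, 4], 3)  # weighted: x plane wins
  expect_equal(f2$dz[3, 4, 4], 0)
})

test_that("invalid masks are rejected", {
  expect_error(compute_dvf(array(1L, c(3, 3, 3))), "background")
  expect_error(as_instance_mask(array(-1L, c(2, 2, 2))), "non-negative")
})

test_that("losses satisfy their identities and match a naive oracle", {
  mk <- random_mask(dims = c(5, 6, 7), seed = 3)
  gt <- compute_dvf(mk)
  expect_equal(displacement_loss(gt, gt), 0)
  expect_equal(direction_loss(gt, gt), 0)
  expect_equal(total_loss(gt, gt), 0)

  # constant offset (1,1,1) gives Ld = 1
  off <- as_dvf(gt$dx + 1, gt$dy + 1, gt$dz + 1)
  expect_equal(displacement_loss(off, gt), 1)

  # anti-parallel and orthogonal fields
  ones <- array(1, dim(mk))
  zeros <- array(0, dim(mk))
  fx <- as_dvf(ones, zeros, zeros)
  expect_equal(direction_loss(as_dvf(-ones, zeros, zeros), fx), 2)
  expect_equal(direction_loss(as_dvf(zeros, ones, zeros), fx), 1)

  # naive elementwise oracle on random fields
  withr::with_seed(11, {
    p <- as_dvf(array(rnorm(60), c(3, 4, 5)), array(rnorm(60), c(3, 4, 5)),
                array(rnorm(60), c(3, 4, 5)))
    g <- as_dvf(array(rnorm(60), c(3, 4, 5)), array(rnorm(60), c(3, 4, 5)),
                array(rnorm(60), c(3, 4, 5)))
  })
  acc <- 0
  for (i in 1:60) {
    acc <- acc + (p$dx[i] - g$dx[i])^2 + (p$dy[i] - g$dy[i])^2 +
      (p$dz[i] - g$dz[i])^2
  }
  expect_equal(displacement_loss(p, g), acc / (3 * 60))

  # total loss is linear with the default weights 7 and 1
  w <- loss_weights()
  expect_equal(w$omega1, 7)
  expect_equal(w$omega2, 1)
  expect_equal(total_loss(p, g, w),
               7 * displacement_loss(p, g) + direction_loss(p, g))
})

test_that("direction loss warns and returns 0 when no voxel is valid", {
  z <- array(0, c(2, 2, 2))
  f <- as_dvf(z, z, z)
  expect_warning(val <- direction_loss(f, f), "no voxel")
  expect_equal(val, 0)
})

test_that("EDT equivalence holds for generated phantoms", {
  ph <- make_phantom(phantom_config(shape = c(12, 28, 28), n_cells = 2,
                                    r_range = c(2.5, 3.5), min_sep = 9,
                                    seed = 4))
  f <- compute_dvf(ph$mask)
  expect_equal(dvf_to_distance(f), brute_force_edt(ph$mask))
})
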