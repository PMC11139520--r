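test_that("the network maps a cube to a 3-channel field of the same shape", {
  cfg <- model_config(levels = 3, channels = c(4, 6, 8), seed = 1)
  net <- build_model(cfg)
  dims <- c(8, 8, 8)
  x <- matrix(0, 1, prod(dims))
  out <- cellasr:::net_forward_mat(net$params, cfg, x, dims)
  expect_equal(dim(out), c(3L, prod(dims)))
  # determinism: identical forward passes
  withr::with_seed(2, x2 <- matrix(rnorm(prod(dims)), 1))
  o1 <- cellasr:::net_forward_mat(net$params, cfg, x2, dims)
  o2 <- cellasr:::net_forward_mat(net$params, cfg, x2, dims)
  expect_identical(o1, o2)
  # shape not divisible by 2^(levels-1) is rejected
  expect_error(cellasr:::net_forward_mat(net$params, cfg, matrix(0, 1, 6 * 8 * 8),
                                         c(6, 8, 8)), "divisible")
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(levels = 2, channels = c(3, 5), seed = 42)
  net <- build_model(cfg)
  dims <- c(4, 4, 4)
  withr::with_seed(7, {
    x <- matrix(rnorm(prod(dims)), 1)
    G <- matrix(rnorm(3 * prod(dims)) * 2, 3)
  })
  # displacement term only: the direction term is non-smooth at the valid-set
  # boundary, which finite differences cannot probe reliably
  w <- loss_weights(7, 0)
  lossfun <- function(par) {
    cellasr:::net_loss_grad(cellasr:::net_forward_mat(par, cfg, x, dims), G, w)$loss
  }
  fw <- cellasr:::net_forward_mat(net$params, cfg, x, dims, cache = TRUE)
  gr <- cellasr:::net_backward_mat(net$params, cfg, fw$cache,
                                   cellasr:::net_loss_grad(fw$out, G, w)$grad)
  withr::with_seed(8, {
    for (nm in names(net$params)) {
      for (k in sample(length(net$params[[nm]]), min(3, length(net$params[[nm]])))) {
        eps <- 1e-5
        p2 <- net$params; p2[[nm]][k] <- p2[[nm]][k] + eps
        p3 <- net$params; p3[[nm]][k] <- p3[[nm]][k] - eps
        fd <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
        expect_equal(gr[[nm]][k], fd, tolerance = 1e-4,
                     label = sprintf("gradient of %s[%d]", nm, k))
      }
    }
  })
})

test_that("training is deterministic and reduces the loss", {
  ph <- make_phantom(phantom_config(shape = c(8, 16, 16), n_cells = 1,
                                    r_range = c(2.5, 3), min_sep = 5, seed = 6))
  cfg <- model_config(levels = 2, channels = c(6, 10), seed = 3)
  fit1 <- train_dvf_net(list(list(volume = ph$volume, mask = ph$mask)),
                        cfg, cube_spec(c(8, 16, 16)), epochs = 30,
                        cubes_per_epoch = 1)
  fit2 <- train_dvf_net(list(list(volume = ph$volume, mask = ph$mask)),
                        cfg, cube_spec(c(8, 16, 16)), epochs = 30,
                        cubes_per_epoch = 1)
  expect_identical(fit1$history, fit2$history)
  h <- fit1$history
  expect_lt(tail(h$loss, 1), h$loss[1])
  expect_equal(nrow(h), 30L)
})

test_that("prediction covers arbitrary volume shapes via cube assembly", {
  cfg <- model_config(levels = 2, channels = c(4, 6), seed = 9)
  net <- build_model(cfg)
  net$cube <- cube_spec(c(8, 16, 16))
  withr::with_seed(10, v <- array(runif(12 * 20 * 24), c(12, 20, 24)))
  f <- predict_dvf(v, net)
  expect_s3_class(f, "dvf_field")
  expect_equal(dim(f), dim(v))
})

test_that("model save/load round-trips weights exactly", {
  cfg <- model_config(levels = 2, channels = c(3, 4), seed = 5)
  net <- build_model(cfg)
  net$cube <- cube_spec(c(8, 8, 8))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(net, path)
  net2 <- load_model(path)
  expect_equal(net2$params, net$params)
  expect_equal(net2$cfg$channels, cfg$channels)
  dims <- c(8, 8, 8)
  withr::with_seed(2, x <- matrix(rnorm(prod(dims)), 1))
  expect_equal(cellasr:::net_forward_mat(net2$params, net2$cfg, x, dims),
               cellasr:::net_forward_mat(net$params, cfg, x, dims))
})
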