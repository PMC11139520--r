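#' Configuration of the DVF regression network
#'
#' A 3D encoder--decoder (U-Net style) regression network mapping a one-channel
#' intensity cube to a three-channel displacement vector field of the same
#' spatial shape.  The default desk-scale configuration (3 levels with
#' 16/32/64 channels on 16x32x32 cubes) trains in minutes on one CPU; the
#' full-scale variant used for real stacks (5 levels, 32/64/128/256/512
#' channels, 80x128x128 cubes) is expressed with the same arguments.
#'
#' @param levels Number of resolution levels (encoder depth).
#' @param channels Integer vector of feature channels per level; its length
#'   must equal `levels`.
#' @param lr Adam learning rate.
#' @param epochs Default number of training epochs.
#' @param seed Integer seed controlling weight initialisation and cube
#'   sampling.
#' @return A `model_config` object.
#' @export
model_config <- function(levels = 3L, channels = c(16L, 32L, 64L),
                         lr = 1e-3, epochs = 5L, seed = 1L) {
  levels <- as.integer(levels)
  channels <- as.integer(channels)
  if (length(channels) != levels) abort("length(channels) must equal levels")
  if (levels < 2L) abort("at least 2 levels are required")
  structure(list(levels = levels, channels = channels, lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "model_config")
}

conv_names <- function(cfg) {
  L <- cfg$levels
  nm <- character(0)
  for (l in seq_len(L)) nm <- c(nm, sprintf("e%da", l), sprintf("e%db", l))
  for (l in rev(seq_len(L - 1))) nm <- c(nm, sprintf("d%da", l), sprintf("d%db", l))
  c(nm, "head")
}

conv_io <- function(cfg, name) {
  ch <- cfg$channels
  if (name == "head") return(c(ch[1], 3L))
  l <- as.integer(substr(name, 2, 2))
  kind <- substr(name, 1, 1)
  ab <- substr(name, 3, 3)
  if (kind == "e") {
    cin <- if (ab == "a") { if (l == 1L) 1L else ch[l - 1L] } else ch[l]
    c(cin, ch[l])
  } else {
    cin <- if (ab == "a") ch[l + 1L] + ch[l] else ch[l]
    c(cin, ch[l])
  }
}

#' Build an untrained DVF regression network
#'
#' Weights are He-initialised deterministically from `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return A `dvf_net` object (parameters, config, empty training history).
#' @export
build_model <- function(cfg = model_config()) {
  par <- withr::with_seed(cfg$seed, {
    p <- list()
    for (nm in conv_names(cfg)) {
      io <- conv_io(cfg, nm)
      k <- if (nm == "head") 1L else 27L
      sdv <- sqrt(2 / (k * io[1]))
      p[[paste0(nm, ".W")]] <- matrix(rnorm(io[2] * io[1] * k, sd = sdv),
                                      io[2], io[1] * k)
      p[[paste0(nm, ".b")]] <- numeric(io[2])
    }
    p
  })
  structure(list(params = par, cfg = cfg, history = NULL), class = "dvf_net")
}

#' @export
print.dvf_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<dvf_net> %d levels (%s channels), %s parameters%s\n",
              x$cfg$levels, paste(x$cfg$channels, collapse = "/"),
              format(np, big.mark = ","),
              if (is.null(x$history)) ", untrained" else ", trained"))
  invisible(x)
}

up_index <- function(dims_child) {
  dp <- dims_child %/% 2L
  pz <- (seq_len(dims_child[1]) + 1L) %/% 2L
  py <- (seq_len(dims_child[2]) + 1L) %/% 2L
  px <- (seq_len(dims_child[3]) + 1L) %/% 2L
  as.vector(outer(outer(pz, (py - 1L) * dp[1], "+"),
                  (px - 1L) * dp[1] * dp[2], "+"))
}

# leaky rectifier (slope 0.1): avoids the dead-unit collapse that a hard
# rectifier suffers on this regression task, where the all-zero output is a
# strong local attractor (most voxels are background)
leaky_relu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
leaky_relu_grad <- function(pre) (pre > 0) + 0.1 * (pre <= 0)

check_net_dims <- function(cfg, dims) {
  div <- 2^(cfg$levels - 1L)
  if (any(dims %% div != 0)) {
    abort(sprintf("cube dims (%s) must be divisible by 2^(levels-1) = %d",
                  paste(dims, collapse = "x"), div))
  }
}

net_forward_mat <- function(par, cfg, x, dims, cache = FALSE) {
  check_net_dims(cfg, dims)
  L <- cfg$levels
  cc <- list(dims = list(), xin = list(), pre = list(), pool_idx = list(),
             pool_nin = list(), up_idx = list())
  d <- dims
  cur <- x
  skips <- list()
  for (l in seq_len(L)) {
    for (ab in c("a", "b")) {
      nm <- sprintf("e%d%s", l, ab)
      if (cache) cc$xin[[nm]] <- cur
      pre <- cpp_conv3d_forward(cur, par[[paste0(nm, ".W")]],
                                par[[paste0(nm, ".b")]], d[1], d[2], d[3])
      if (cache) cc$pre[[nm]] <- pre
      cur <- leaky_relu(pre)
      if (cache) cc$dims[[nm]] <- d
    }
    if (l < L) {
      skips[[l]] <- cur
      pl <- cpp_maxpool_fwd(cur, d[1], d[2], d[3])
      if (cache) {
        cc$pool_idx[[l]] <- pl$idx
        cc$pool_nin[[l]] <- ncol(cur)
      }
      cur <- pl$out
      d <- d %/% 2L
    }
  }
  for (l in rev(seq_len(L - 1))) {
    d <- d * 2L
    ui <- up_index(d)
    if (cache) cc$up_idx[[l]] <- ui
    cur <- rbind(cur[, ui, drop = FALSE], skips[[l]])
    for (ab in c("a", "b")) {
      nm <- sprintf("d%d%s", l, ab)
      if (cache) cc$xin[[nm]] <- cur
      pre <- cpp_conv3d_forward(cur, par[[paste0(nm, ".W")]],
                                par[[paste0(nm, ".b")]], d[1], d[2], d[3])
      if (cache) cc$pre[[nm]] <- pre
      cur <- leaky_relu(pre)
      if (cache) cc$dims[[nm]] <- d
    }
  }
  if (cache) cc$xin[["head"]] <- cur
  out <- par[["head.W"]] %*% cur + par[["head.b"]]
  if (cache) list(out = out, cache = cc) else out
}

net_backward_mat <- function(par, cfg, cc, gout) {
  L <- cfg$levels
  gr <- list()
  g <- gout
  # head (1x1 conv)
  gr[["head.W"]] <- g %*% t(cc$xin[["head"]])
  gr[["head.b"]] <- rowSums(g)
  g <- t(par[["head.W"]]) %*% g
  conv_bwd <- function(nm, g) {
    d <- cc$dims[[nm]]
    g <- g * leaky_relu_grad(cc$pre[[nm]])
    bb <- cpp_conv3d_backward(cc$xin[[nm]], par[[paste0(nm, ".W")]],
                              g, d[1], d[2], d[3])
    gr[[paste0(nm, ".W")]] <<- bb$gW
    gr[[paste0(nm, ".b")]] <<- as.numeric(bb$gb)
    bb$gin
  }
  # decoder stages in reverse execution order (stage 1 ran last); each stage's
  # up-sampled half propagates to the next-deeper stage, the other half to the
  # encoder skip connection
  gskip <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    g <- conv_bwd(sprintf("d%db", l), g)
    g <- conv_bwd(sprintf("d%da", l), g)
    ch_up <- cfg$channels[l + 1]
    gup <- g[seq_len(ch_up), , drop = FALSE]
    gskip[[l]] <- g[-seq_len(ch_up), , drop = FALSE]
    # nearest-neighbour upsample backward: sum gradients over children
    g <- t(rowsum(t(gup), group = cc$up_idx[[l]]))
  }
  # encoder from the bottleneck up; g currently holds the bottleneck gradient
  for (l in rev(seq_len(L))) {
    if (l < L) g <- g + gskip[[l]]
    g <- conv_bwd(sprintf("e%db", l), g)
    g <- conv_bwd(sprintf("e%da", l), g)
    if (l > 1) g <- cpp_maxpool_bwd(g, cc$pool_idx[[l - 1]], cc$pool_nin[[l - 1]])
  }
  gr
}

# Loss and gradient on (3 x N) prediction/target matrices.  The training
# surrogate of the direction loss restricts the mean to ground-truth
# foreground voxels and floors the predicted norm in the cosine denominator
# at `delta`: without the floor the cosine gradient scales like 1/|p| and
# swamps the displacement gradient with noise whenever predictions are near
# zero (which is exactly the early-training regime).  The evaluation-side
# direction_loss() is unaffected.
net_loss_grad <- function(P, G, w, eps = 1e-8, delta = 0.5) {
  n <- ncol(P)
  diffm <- P - G
  ld <- sum(diffm^2) / (3 * n)
  grad <- (2 / (3 * n)) * diffm * w$omega1
  ng <- sqrt(colSums(G^2))
  valid <- ng > eps
  nv <- sum(valid)
  if (nv > 0) {
    Pv <- P[, valid, drop = FALSE]
    Gv <- G[, valid, drop = FALSE]
    np <- sqrt(colSums(Pv^2))
    npf <- pmax(np, delta)
    ngv <- ng[valid]
    cosv <- colSums(Pv * Gv) / (npf * ngv)
    lr <- 1 - sum(cosv) / nv
    gcos <- sweep(Gv, 2, npf * ngv, "/")
    free <- np > delta  # norm term only active where the floor is not
    if (any(free)) {
      gcos[, free] <- gcos[, free] -
        sweep(Pv[, free, drop = FALSE], 2, cosv[free] / npf[free]^2, "*")
    }
    grad[, valid] <- grad[, valid] - (w$omega2 / nv) * gcos
  } else {
    lr <- 0
  }
  list(loss = w$omega1 * ld + w$omega2 * lr, ld = ld, lr = lr, grad = grad)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, gr, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    g <- gr[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, st = st)
}

normalize_volume <- function(vol) {
  rng <- range(vol)
  if (rng[2] > rng[1]) (vol - rng[1]) / (rng[2] - rng[1]) else vol * 0
}

#' Train the DVF regression network on image/mask pairs
#'
#' Each epoch samples `cubes_per_epoch` random cube origins from every
#' training volume, computes the ground-truth displacement field of the
#' corresponding mask crop with [compute_dvf()], and performs one Adam step on
#' the combined loss `omega1 * Ld + omega2 * Lr` per cube.  Intensities are
#' min-max normalised per volume.  Fully deterministic given `cfg$seed`.
#'
#' @param pairs A list of `list(volume =, mask =)` training pairs; every
#'   volume must be at least as large as the cube shape.
#' @param cfg A [model_config()].
#' @param cube A [cube_spec()]; its `shape` is the training crop size.
#' @param weights A [loss_weights()].
#' @param epochs Number of epochs (defaults to `cfg$epochs`).
#' @param cubes_per_epoch Random cubes sampled per volume per epoch.
#' @param model Optionally, a previously built/trained `dvf_net` to continue
#'   from; defaults to a fresh [build_model()].
#' @return A trained `dvf_net` whose `history` is a tibble with one row per
#'   optimisation step (`epoch`, `step`, `loss`, `ld`, `lr`).
#' @export
train_dvf_net <- function(pairs, cfg = model_config(), cube = cube_spec(),
                          weights = loss_weights(), epochs = cfg$epochs,
                          cubes_per_epoch = 8L, model = NULL) {
  if (length(pairs) < 1) abort("at least one training pair is required")
  if (is.null(model)) model <- build_model(cfg)
  par <- model$params
  sh <- cube$shape
  vols <- lapply(pairs, function(p) normalize_volume(as_volume(p$volume)))
  masks <- lapply(pairs, function(p) as_instance_mask(p$mask))
  for (v in vols) {
    if (any(dim(v) < sh)) abort("training volumes must be >= the cube shape")
  }
  st <- adam_init(par)
  hist <- list()
  step <- 0L
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(epochs)) {
      for (i in seq_along(vols)) {
        d <- dim(vols[[i]])
        for (k in seq_len(cubes_per_epoch)) {
          mk <- NULL
          for (try in 1:20) {
            o <- c(sample.int(d[1] - sh[1] + 1L, 1L),
                   sample.int(d[2] - sh[2] + 1L, 1L),
                   sample.int(d[3] - sh[3] + 1L, 1L))
            mk <- masks[[i]][o[1]:(o[1] + sh[1] - 1L),
                             o[2]:(o[2] + sh[2] - 1L),
                             o[3]:(o[3] + sh[3] - 1L), drop = FALSE]
            if (any(mk == 0)) break
            mk <- NULL
          }
          if (is.null(mk)) {
            warn("sampled cubes contain no background; skipping one sample")
            next
          }
          vc <- vols[[i]][o[1]:(o[1] + sh[1] - 1L),
                          o[2]:(o[2] + sh[2] - 1L),
                          o[3]:(o[3] + sh[3] - 1L), drop = FALSE]
          gt <- compute_dvf(mk)
          G <- dvf_mat(gt)
          fw <- net_forward_mat(par, cfg, matrix(as.vector(vc), 1L), sh,
                                cache = TRUE)
          lg <- net_loss_grad(fw$out, G, weights)
          gr <- net_backward_mat(par, cfg, fw$cache, lg$grad)
          upd <- adam_step(par, gr, st, cfg$lr)
          par <- upd$par
          st <- upd$st
          step <- step + 1L
          hist[[step]] <- c(epoch = ep, step = step, loss = lg$loss,
                            ld = lg$ld, lr = lg$lr)
        }
      }
    }
  })
  model$params <- par
  model$cfg <- cfg
  model$cube <- cube
  model$weights <- weights
  model$history <- as_tibble(do.call(rbind, hist))
  model
}

#' Predict a displacement vector field for a whole volume
#'
#' The volume is min-max normalised, partitioned into cubes
#' ([partition_volume()]), each cube is pushed through the network, and the
#' per-cube fields are reassembled with mean blending over any overlaps
#' ([assemble_cubes()]).
#'
#' @param vol A 3D intensity array.
#' @param model A trained `dvf_net`.
#' @param cube A [cube_spec()]; defaults to the one used in training.
#' @return A `dvf_field` with the same spatial shape as `vol`.
#' @export
predict_dvf <- function(vol, model, cube = NULL) {
  vol <- normalize_volume(as_volume(vol))
  cube <- cube %||% model$cube %||% cube_spec()
  pieces <- partition_volume(vol, cube)
  pieces$cube <- lapply(pieces$cube, function(cb) {
    out <- net_forward_mat(model$params, model$cfg,
                           matrix(as.vector(cb), 1L), dim(cb))
    array(t(out), c(dim(cb), 3L)) |> aperm(c(4L, 1L, 2L, 3L))
  })
  full <- assemble_cubes(pieces, dim(vol))
  as_dvf(array(full[1, , , ], dim(vol)),
         array(full[2, , , ], dim(vol)),
         array(full[3, , , ], dim(vol)))
}
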