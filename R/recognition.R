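#' Extract cell centroids from an instance mask
#'
#' Per-label mean voxel coordinate, converted to world `(x, y, z)` order
#' (1-based voxel centres), ordered by label.
#'
#' @param mask An instance mask.
#' @return A `cell_points` tibble with a `label` column.
#' @export
extract_centroids <- function(mask) {
  mask <- as_instance_mask(mask)
  if (all(mask == 0)) abort("mask has no instances")
  d <- dim(mask)
  v <- as.vector(mask)
  idx <- which(v > 0)
  lab <- v[idx]
  iz <- ((idx - 1L) %% d[1]) + 1L
  iy <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  ix <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  labs <- sort(unique(lab))
  grp <- match(lab, labs)
  n <- tabulate(grp)
  out <- tibble(
    label = labs,
    x = as.numeric(rowsum(as.numeric(ix), grp)) / n,
    y = as.numeric(rowsum(as.numeric(iy), grp)) / n,
    z = as.numeric(rowsum(as.numeric(iz), grp)) / n
  )
  cp <- cell_points(tibble(id = NA_character_, x = out$x, y = out$y, z = out$z))
  cp$label <- out$label
  cp
}

#' Recognition pipeline configuration
#'
#' Annealing and matching parameters for identity assignment.  `alpha` is the
#' spatial temperature (decayed by `anneal_rate` each step until it falls
#' below `alpha_min`), `beta` the shape-context temperature (grown by the
#' same rate), so spatial position dominates early and local topology
#' fine-tunes late.  `alpha0`/`beta0` default to data-driven values: the mean
#' squared nearest-neighbour distance of the target, and the value equating
#' the median magnitudes of the two exponent terms.
#'
#' @param alpha0,beta0 Initial temperatures (`NULL` = data-driven).
#' @param anneal_rate Multiplicative decay in `(0, 1)`.
#' @param alpha_min Annealing stops when `alpha < alpha_min`.
#' @param omega Constant scale of the prior similarity kernels.
#' @param max_outer_iter Maximum map/refine iterations.
#' @param n_segments,overlap Piecewise-affine mapping settings.
#' @param sinkhorn_iter Row/column normalisation sweeps per annealing step.
#' @param priors Character subset of `c("spv", "tsv")`: which atlas priors
#'   drive the refinement and final assignment (empty = average positions
#'   only).
#' @return A `recognition_config` object.
#' @export
recognition_config <- function(alpha0 = NULL, beta0 = NULL, anneal_rate = 0.93,
                               alpha_min = 0.1, omega = 1,
                               max_outer_iter = 10L, n_segments = 8L,
                               overlap = 0.2, sinkhorn_iter = 5L,
                               priors = c("spv", "tsv")) {
  if (anneal_rate <= 0 || anneal_rate >= 1) abort("anneal_rate must be in (0, 1)")
  stopifnot(all(priors %in% c("spv", "tsv")))
  structure(list(alpha0 = alpha0, beta0 = beta0, anneal_rate = anneal_rate,
                 alpha_min = alpha_min, omega = omega,
                 max_outer_iter = as.integer(max_outer_iter),
                 n_segments = as.integer(n_segments), overlap = overlap,
                 sinkhorn_iter = as.integer(sinkhorn_iter), priors = priors),
            class = "recognition_config")
}

#' PCA-based rigid/scale pre-alignment of two point sets
#'
#' Centres both sets, rotates the subject's principal axes onto the target's,
#' and scales each axis by the ratio of standard deviations.  Among the four
#' proper-rotation sign choices the one minimising the symmetric Chamfer
#' distance is returned; reflections are never applied.
#'
#' @param subject,target `cell_points` tibbles or n x 3 matrices (>= 4
#'   points, non-degenerate covariance).
#' @return An `affine3d` mapping subject into the target frame.
#' @export
pca_align <- function(subject, target) {
  S <- if (is.matrix(subject)) subject else pts_mat(subject)
  Tm <- if (is.matrix(target)) target else pts_mat(target)
  if (nrow(S) < 4 || nrow(Tm) < 4) abort("at least 4 points are required")
  ps <- prcomp(S, center = TRUE)
  pt <- prcomp(Tm, center = TRUE)
  if (any(ps$sdev < 1e-12) || any(pt$sdev < 1e-12)) {
    abort("rank-deficient point configuration")
  }
  pca_align_candidates(S, Tm)[[1]]
}

# all four proper-rotation pose hypotheses, ordered by symmetric Chamfer
# distance; used to protect the matching stage against head-tail flips of
# nearly symmetric bodies
pca_align_candidates <- function(subject, target) {
  S <- if (is.matrix(subject)) subject else pts_mat(subject)
  Tm <- if (is.matrix(target)) target else pts_mat(target)
  ps <- prcomp(S, center = TRUE)
  pt <- prcomp(Tm, center = TRUE)
  if (any(ps$sdev < 1e-12) || any(pt$sdev < 1e-12)) {
    abort("rank-deficient point configuration")
  }
  Rs0 <- ps$rotation
  if (det(Rs0) < 0) Rs0[, 3] <- -Rs0[, 3]
  Rt0 <- pt$rotation
  if (det(Rt0) < 0) Rt0[, 3] <- -Rt0[, 3]
  cands <- list()
  costs <- numeric(0)
  for (sgn in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    Rs <- Rs0 %*% diag(sgn)
    A <- Rt0 %*% diag(pt$sdev / ps$sdev) %*% t(Rs)
    tf <- affine3d(A = A, t = as.numeric(colMeans(Tm) - A %*% colMeans(S)))
    cands[[length(cands) + 1]] <- tf
    costs <- c(costs, chamfer_distance(apply_transform(S, tf), Tm))
  }
  cands[order(costs)]
}

chamfer_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))
}

euclid_cross <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

mean_sq_nn <- function(M) {
  d <- euclid_cross(M, M)
  diag(d) <- Inf
  mean(apply(d, 1, min)^2)
}

#' Initial correspondence by annealed robust point matching
#'
#' Deterministic-annealing soft assignment between subject and target points.
#' The point-pair similarity is `exp(-(d/alpha + g/beta))` with `d` the
#' Euclidean distance and `g` the chi-square distance between shape contexts;
#' an outlier slack row/column with constant score `exp(-1)` absorbs
#' unmatchable points.  Each annealing step alternates row/column
#' normalisation of the similarity matrix, re-fits an affine transform from
#' the soft correspondences, recomputes the subject's (pose-dependent) shape
#' contexts, then decays `alpha` and grows `beta`.  On termination, hard
#' one-to-one correspondences are extracted by the assignment solver on
#' `-log f`.  With `beta0 = Inf` the shape term vanishes and the procedure
#' reduces to purely spatial robust point matching.
#'
#' @param subject,target `cell_points` tibbles or n x 3 matrices; the subject
#'   should already be roughly aligned (see [pca_align()]).
#' @param cfg A [recognition_config()].
#' @param sc_params A [shape_context_params()].
#' @param sc_target Optional precomputed target shape contexts.
#' @return A `match_state`: list with `correspondences` (tibble `subject`,
#'   `target`), `soft` (the final soft matrix), `transform` (fitted
#'   `affine3d`), `alpha`, `beta`, `iterations`.
#' @export
rpm_match <- function(subject, target, cfg = recognition_config(),
                      sc_params = shape_context_params(), sc_target = NULL) {
  S0 <- if (is.matrix(subject)) subject else pts_mat(subject)
  Tm <- if (is.matrix(target)) target else pts_mat(target)
  N <- nrow(S0); M <- nrow(Tm)
  tframe <- pca_frame(Tm)
  if (is.null(sc_target)) sc_target <- shape_context_all(Tm, sc_params, frame = tframe)
  alpha <- cfg$alpha0 %||% mean_sq_nn(Tm)
  S <- S0
  tf <- affine3d()
  g <- if (is.finite(cfg$beta0 %||% 1)) {
    chi_square_cross(shape_context_all(S, sc_params, frame = tframe), sc_target)
  } else {
    matrix(0, N, M)
  }
  d <- euclid_cross(S, Tm)
  beta <- cfg$beta0 %||% {
    mg <- median(g)
    if (mg <= 0) Inf else mg * alpha / max(median(d), 1e-12)
  }
  it <- 0L
  soft <- NULL
  while (alpha >= cfg$alpha_min) {
    it <- it + 1L
    d <- euclid_cross(S, Tm)
    expo <- d / alpha + (if (is.finite(beta)) g / beta else 0)
    f <- pmax(exp(-expo), 1e-300)
    aug <- rbind(cbind(f, exp(-1)), c(rep(exp(-1), M), exp(-1)))
    for (k in seq_len(cfg$sinkhorn_iter)) {
      aug <- aug / rowSums(aug)
      aug <- sweep(aug, 2, colSums(aug), "/")
    }
    soft <- aug[seq_len(N), seq_len(M), drop = FALSE]
    w <- rowSums(soft)
    yt <- (soft %*% Tm) / w
    tf <- fit_affine(S0, yt, correspondences = cbind(seq_len(N), seq_len(N)),
                     weights = w)
    S <- apply_transform(S0, tf)
    if (is.finite(beta)) {
      g <- chi_square_cross(shape_context_all(S, sc_params, frame = tframe),
                            sc_target)
    }
    alpha <- alpha * cfg$anneal_rate
    if (is.finite(beta)) beta <- beta / cfg$anneal_rate
  }
  d <- euclid_cross(S, Tm)
  cost <- d / max(alpha, cfg$alpha_min) + (if (is.finite(beta)) g / beta else 0)
  corr <- solve_assignment(cost)
  structure(list(
    correspondences = corr,
    soft = soft,
    transform = tf,
    alpha = alpha, beta = beta, iterations = it
  ), class = "match_state")
}

#' Minimum-cost one-to-one assignment
#'
#' Solves the rectangular linear assignment problem (Hungarian/
#' Jonker-Volgenant style shortest augmenting paths).  When the cost matrix
#' is rectangular the smaller side is fully assigned; the larger side's
#' unassigned items are left out.
#'
#' @param cost A numeric cost matrix (finite values).
#' @return A tibble with columns `subject` (row) and `target` (assigned
#'   column), one row per assigned pair.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) <= ncol(cost)) {
    j <- cpp_assignment(cost)
    tibble(subject = seq_len(nrow(cost)), target = as.integer(j))
  } else {
    i <- cpp_assignment(t(cost))
    tibble(subject = as.integer(i), target = seq_len(ncol(cost)))
  }
}

#' Map the subject onto the target through current correspondences
#'
#' Fits a global affine followed by a piecewise-affine transform on the
#' current correspondence pairs and applies both to all subject points.
#'
#' @param subject,target `cell_points` tibbles or n x 3 matrices.
#' @param correspondences Tibble/matrix of (subject row, target row) pairs.
#' @param n_segments,overlap Piecewise-affine settings.
#' @return The mapped subject (same type as the input).
#' @export
map_subject <- function(subject, correspondences, target, n_segments = 8L,
                        overlap = 0.2) {
  cc <- as.matrix(correspondences)[, 1:2, drop = FALSE]
  if (nrow(cc) == 0) abort("empty correspondence list")
  S <- if (is.matrix(subject)) subject else pts_mat(subject)
  Tm <- if (is.matrix(target)) target else pts_mat(target)
  tf1 <- fit_affine(S[cc[, 1], , drop = FALSE], Tm[cc[, 2], , drop = FALSE],
                    correspondences = cbind(seq_len(nrow(cc)), seq_len(nrow(cc))))
  S1 <- apply_transform(S, tf1)
  tf2 <- fit_pwa(S1[cc[, 1], , drop = FALSE], Tm[cc[, 2], , drop = FALSE],
                 n_segments = n_segments, overlap = overlap)
  out <- apply_transform(S1, tf2)
  if (is.matrix(subject)) out else set_pts(subject, out)
}

#' Prior-based similarity kernels
#'
#' `spv_similarity` is the anisotropic Gaussian position kernel
#' `exp(-(1/(2 omega^2)) * || (s - v) / sigma ||^2)`; `tsv_similarity` is the
#' shape-context kernel `exp(-(1/(2 omega^2)) * g^2 / gamma^2)`.  Zero sigma
#' or gamma entries are floored at 1e-6 (with a warning).
#'
#' @param s,v Length-3 positions.
#' @param sigma Per-axis standard deviations of the target cell.
#' @param g Chi-square shape-context distance.
#' @param gamma Shape-context variability of the target cell.
#' @param omega Constant kernel scale.
#' @return A scalar in `(0, 1]`.
#' @export
spv_similarity <- function(s, v, sigma, omega = 1) {
  sigma <- floor_positive(sigma)
  exp(-sum(((s - v) / sigma)^2) / (2 * omega^2))
}

#' @rdname spv_similarity
#' @export
tsv_similarity <- function(g, gamma, omega = 1) {
  gamma <- floor_positive(gamma)
  exp(-(g^2 / gamma^2) / (2 * omega^2))
}

floor_positive <- function(x, eps = 1e-6) {
  if (any(x < eps)) {
    warn("non-positive variability floored at 1e-6")
    x <- pmax(x, eps)
  }
  x
}

# N x M prior similarity matrices between mapped subject points and the atlas
spv_matrix <- function(S, atlas, omega = 1) {
  sig <- pmax(as.matrix(atlas[, c("sx", "sy", "sz")]), 1e-6)
  V <- pts_mat(atlas)
  out <- matrix(0, nrow(S), nrow(V))
  for (ax in 1:3) {
    out <- out + (outer(S[, ax], V[, ax], "-") / matrix(sig[, ax], nrow(S),
                                                        nrow(V), byrow = TRUE))^2
  }
  exp(-out / (2 * omega^2))
}

tsv_matrix <- function(sc_subject, atlas, omega = 1) {
  g <- chi_square_cross(sc_subject, attr(atlas, "sc_ref"))
  gam <- pmax(atlas$gamma, 1e-6)
  exp(-sweep(g^2, 2, gam^2, "/") / (2 * omega^2))
}

#' Consensus bipartite refinement of correspondences
#'
#' Builds the position-prior and topology-prior similarity matrices between
#' the mapped subject and the atlas, solves the assignment problem on each
#' separately, and keeps only the pairs on which both solutions agree
#' exactly.  If the requested priors reduce to a single matrix, its full
#' assignment is returned; if the consensus is empty, the position-prior
#' assignment is used as a fallback (with a warning).
#'
#' @param subject_mapped Subject points already mapped into atlas space.
#' @param atlas A `cell_atlas`.
#' @param cfg A [recognition_config()].
#' @return A tibble of consensus (subject, target) pairs.
#' @export
refine_bipartite <- function(subject_mapped, atlas, cfg = recognition_config()) {
  S <- if (is.matrix(subject_mapped)) subject_mapped else pts_mat(subject_mapped)
  sc_params <- attr(atlas, "sc_params")
  Fspv <- spv_matrix(S, atlas, cfg$omega)
  use_tsv <- "tsv" %in% cfg$priors
  a_spv <- solve_assignment(-log(pmax(Fspv, 1e-300)))
  if (!use_tsv) return(a_spv)
  scs <- shape_context_all(S, sc_params, frame = attr(atlas, "frame"))
  Ftsv <- tsv_matrix(scs, atlas, cfg$omega)
  a_tsv <- solve_assignment(-log(pmax(Ftsv, 1e-300)))
  key_spv <- paste(a_spv$subject, a_spv$target)
  key_tsv <- paste(a_tsv$subject, a_tsv$target)
  consensus <- a_spv[key_spv %in% key_tsv, , drop = FALSE]
  if (nrow(consensus) < 4) {
    # fewer than 4 agreed pairs cannot constrain any spatial map
    warn("near-empty consensus; falling back to the position-prior assignment")
    return(a_spv)
  }
  consensus
}

#' Assign atlas identities to segmented cells
#'
#' The full recognition pipeline: PCA pre-alignment of the subject centroids
#' to the atlas average positions, annealed robust point matching for the
#' initial correspondence, then alternating (affine + piecewise-affine)
#' mapping and consensus bipartite refinement until the correspondence set is
#' stable, and a final assignment on the summed position- and topology-prior
#' similarity matrices.  Deterministic given inputs and configuration.
#'
#' With `cfg$priors = character(0)` the final assignment uses only distances
#' to the average positions; with `"spv"` only the position prior; the
#' default adds the topology prior and the consensus refinement.
#'
#' @param subject A `cell_points` tibble of segmented centroids (>= 4 cells).
#' @param atlas A `cell_atlas`.
#' @param cfg A [recognition_config()].
#' @return A `recognition_result` tibble: one row per subject cell with its
#'   assigned atlas `id` (or `NA`) and a normalised `confidence`.
#' @export
recognize <- function(subject, atlas, cfg = recognition_config()) {
  stopifnot(inherits(atlas, "cell_atlas"))
  subject <- cell_points(subject)
  if (nrow(subject) < 4) abort("at least 4 subject cells are required")
  sc_params <- attr(atlas, "sc_params")
  S0 <- pts_mat(subject)
  # The two most plausible PCA pose hypotheses guard against head-tail flips
  # of nearly symmetric bodies.  Each hypothesis is carried through the full
  # matching pipeline and the one ending with the higher summed prior
  # similarity of its assignment wins; spatial tightness alone cannot
  # discriminate, because a flipped pose also matches tightly on an almost
  # symmetric body.
  pipeline_one <- function(tf0) {
    Sc <- apply_transform(S0, tf0)
    ms <- rpm_match(Sc, pts_mat(atlas), cfg, sc_params)
    S <- apply_transform(Sc, ms$transform)
    corr <- ms$correspondences
    if (length(cfg$priors) > 0) {
      for (it in seq_len(cfg$max_outer_iter)) {
        Smap <- map_subject(S, corr, pts_mat(atlas), cfg$n_segments, cfg$overlap)
        newcorr <- refine_bipartite(Smap, atlas, cfg)
        if (identical(dim(newcorr), dim(corr)) &&
            all(newcorr$subject == corr$subject) &&
            all(newcorr$target == corr$target)) {
          corr <- newcorr
          break
        }
        corr <- newcorr
      }
    }
    Smap <- map_subject(S, corr, pts_mat(atlas), cfg$n_segments, cfg$overlap)
    Sm <- if (is.matrix(Smap)) Smap else pts_mat(Smap)
    final <- final_similarity(Sm, atlas, cfg)
    asg <- solve_assignment(-log(pmax(final, 1e-300)))
    score <- mean(final[cbind(asg$subject, asg$target)])
    list(final = final, asg = asg, Sm = Sm, score = score)
  }
  cands <- utils::head(pca_align_candidates(S0, pts_mat(atlas)), 2)
  runs <- lapply(cands, pipeline_one)
  best <- runs[[which.max(vapply(runs, function(r) r$score, numeric(1)))]]
  final <- best$final
  asg <- best$asg
  Sm <- best$Sm
  conf <- vapply(seq_len(nrow(asg)), function(k) {
    r <- final[asg$subject[k], ]
    r[asg$target[k]] / max(sum(r), 1e-300)
  }, numeric(1))
  out <- tibble(
    subject = asg$subject,
    label = if ("label" %in% names(subject)) subject$label[asg$subject] else asg$subject,
    id = atlas$id[asg$target],
    confidence = conf
  )
  # subject cells not assigned (when N > M) appear with NA id
  if (nrow(out) < nrow(subject)) {
    missing <- setdiff(seq_len(nrow(subject)), out$subject)
    out <- dplyr::bind_rows(out, tibble(
      subject = missing,
      label = if ("label" %in% names(subject)) subject$label[missing] else missing,
      id = NA_character_, confidence = NA_real_
    ))
    out <- out[order(out$subject), ]
  }
  structure(out, class = c("recognition_result", class(out)),
            mapped = Sm, config = cfg)
}

final_similarity <- function(Sm, atlas, cfg) {
  if (length(cfg$priors) == 0) {
    # average-positions only: isotropic unit-sigma Gaussian on distance
    d <- euclid_cross(Sm, pts_mat(atlas))
    return(exp(-d^2 / (2 * cfg$omega^2)))
  }
  Fspv <- spv_matrix(Sm, atlas, cfg$omega)
  if (!("tsv" %in% cfg$priors)) return(Fspv)
  scs <- shape_context_all(Sm, attr(atlas, "sc_params"),
                           frame = attr(atlas, "frame"))
  Fspv + tsv_matrix(scs, atlas, cfg$omega)
}

#' @export
tidy.recognition_result <- function(x, ...) as_tibble(x)

#' @export
glance.recognition_result <- function(x, ...) {
  tibble(n_cells = nrow(x), n_assigned = sum(!is.na(x$id)),
         mean_confidence = mean(x$confidence, na.rm = TRUE))
}

#' Fraction of correctly recognised identities
#'
#' @param result A `recognition_result`.
#' @param truth A `cell_points` tibble with the true `id` per subject row (in
#'   subject order), or a character vector of true ids.
#' @return The fraction of subject cells whose assigned id equals the truth.
#' @export
recognition_accuracy <- function(result, truth) {
  tid <- if (is.character(truth)) truth else cell_points(truth)$id
  stopifnot(length(tid) == nrow(result))
  mean(!is.na(result$id) & result$id == tid[result$subject])
}
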