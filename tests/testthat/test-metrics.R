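make_toy <- function(assign) {
  # assign: list of label -> voxel index vectors in a 1x4x6 grid
  m <- array(0L, c(1, 4, 6))
  for (k in seq_along(assign)) m[assign[[k]]] <- k
  m
}

test_that("all metrics equal 1 on identical labelled masks", {
  mk <- two_sphere_mask(r = 3, sep = 10, pad = 6)
  expect_equal(voxel_accuracy(mk, mk), 1)
  expect_equal(instance_prf(mk, mk)$f1, 1)
  expect_equal(aji(mk, mk), 1)
  expect_equal(iiou(mk, mk), 1)
  expect_equal(ap_at(mk, mk, 0.5), 1)
  expect_equal(ap_range(mk, mk), 1)
})

test_that("voxel accuracy is binary agreement", {
  a <- array(c(1L, 1L, 0L, 0L), c(1, 2, 2))
  b <- array(c(0L, 0L, 1L, 1L), c(1, 2, 2))
  expect_equal(voxel_accuracy(a, b), 0)
  c2 <- array(c(1L, 0L, 0L, 1L), c(1, 2, 2))
  expect_equal(voxel_accuracy(a, c2), 0.5)
  expect_error(voxel_accuracy(a, array(0L, c(1, 2, 3))), "dimensions")
})

test_that("instance matching is one-to-one and matches brute force on toys", {
  gt <- make_toy(list(1:4, 9:12, 17:20))
  pred <- make_toy(list(c(1:3, 5), 9:12))
  m <- match_instances(pred, gt, 0.5)
  expect_equal(nrow(m$pairs), 2L)
  expect_true(!anyDuplicated(m$pairs$pred) && !anyDuplicated(m$pairs$gt))
  expect_equal(sort(m$unmatched_gt), 3L)
  # disjoint masks have no matches
  d1 <- make_toy(list(1:4))
  d2 <- make_toy(list(9:12))
  expect_equal(nrow(match_instances(d1, d2, 0.5)$pairs), 0L)
})

test_that("precision/recall/F1 follow the TP/FP/FN counts", {
  gt <- make_toy(list(1:4, 9:12, 17:20))
  pred <- make_toy(list(1:4, 9:12, 21:24))  # 2 TP, 1 FP, 1 FN
  prf <- instance_prf(pred, gt, 0.5)
  expect_equal(prf$precision, 2 / 3)
  expect_equal(prf$recall, 2 / 3)
  expect_equal(prf$f1, 2 / 3)
  empty <- make_toy(list())
  expect_equal(unlist(instance_prf(empty, gt, 0.5)), c(precision = 0,
                                                       recall = 0, f1 = 0))
})

test_that("AJI equals hand-enumerated values on a two-cell toy", {
  gt <- make_toy(list(1:4, 9:12))
  pred <- make_toy(list(1:3, c(9:12, 13)))
  # cell 1: inter 3, union 4; cell 2: inter 4, union 5; no unmatched pred
  expect_equal(aji(pred, gt), (3 + 4) / (4 + 5))
  # an unmatched prediction enters the denominator
  pred2 <- make_toy(list(1:3, c(9:12, 13), 17:20))
  expect_equal(aji(pred2, gt), (3 + 4) / (4 + 5 + 4))
  expect_equal(aji(make_toy(list(17:20)), gt), 0)
  expect_error(aji(gt, make_toy(list())), "no instances")
})

test_that("IIoU weighs every ground-truth cell equally", {
  # 8-voxel GT cell; prediction covers 4 of them plus 4 outside -> 4/12
  gt <- make_toy(list(1:8))
  pred <- make_toy(list(c(1:4, 13:16)))
  expect_equal(iiou(pred, gt), 1 / 3)
  # small and large cell each half-covered: mean of the two IoUs
  gt2 <- make_toy(list(1:2, 9:16))
  pred2 <- make_toy(list(1L, 9:12))
  expect_equal(iiou(pred2, gt2), mean(c(1 / 2, 4 / 8)))
  # an unmatched GT cell contributes zero
  expect_equal(iiou(make_toy(list(1:2)), gt2), mean(c(1, 0)))
})

test_that("AP@t is TP/(TP+FP+FN) and non-increasing in t", {
  gt <- make_toy(list(1:4, 9:12, 17:20))
  pred <- make_toy(list(1:4, 21:24))  # 1 TP, 1 FP, 2 FN
  expect_equal(ap_at(pred, gt, 0.5), 1 / 4)
  pred2 <- make_toy(list(c(1:3, 5), 9:12))
  aps <- vapply(seq(0.5, 0.95, 0.05), function(t) ap_at(pred2, gt, t),
                numeric(1))
  expect_true(all(diff(aps) <= 0))
  expect_equal(ap_range(pred2, gt), mean(aps))
})

test_that("recognition AP requires both overlap and identity", {
  gt <- make_toy(list(1:4, 9:12))
  ids_gt <- tibble::tibble(label = 1:2, id = c("a", "b"))
  # perfect segmentation + perfect identities
  expect_equal(recognition_ap(gt, gt, ids_gt, ids_gt, 0.5), 1)
  # identities permuted: zero
  ids_swap <- tibble::tibble(label = 1:2, id = c("b", "a"))
  expect_equal(recognition_ap(gt, gt, ids_swap, ids_gt, 0.5), 0)
  # half the identities correct on perfect segmentation:
  # 1 TP, 1 FP (wrong id), 1 FN -> 1/3
  ids_half <- tibble::tibble(label = 1:2, id = c("a", "zzz"))
  expect_equal(recognition_ap(gt, gt, ids_half, ids_gt, 0.5), 1 / 3)
  # a missing identity entry counts as a false positive
  ids_missing <- tibble::tibble(label = 1L, id = "a")
  expect_equal(recognition_ap(gt, gt, ids_missing, ids_gt, 0.5), 1 / 3)
})
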