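#' Segmentation and recognition evaluation metrics
#'
#' Instance-level metrics operate on pairs of labelled masks.  Conventions:
#' voxel accuracy is binary foreground/background agreement;
#' precision/recall/F1 are instance-level at an IoU threshold (default 0.5);
#' `AP@t = TP / (TP + FP + FN)`; AJI is the aggregated Jaccard index; IIoU is
#' the mean per-ground-truth-cell IoU, weighting every cell equally regardless
#' of size.
#'
#' @name segmentation-metrics
NULL

# pairwise IoU bookkeeping between two labelled masks
iou_pairs <- function(pred, gt) {
  pv <- as.vector(pred)
  gv <- as.vector(gt)
  keep <- pv > 0L | gv > 0L
  pv <- pv[keep]; gv <- gv[keep]
  psize <- tabulate(pv)
  gsize <- tabulate(gv)
  both <- pv > 0L & gv > 0L
  if (any(both)) {
    key <- paste(pv[both], gv[both])
    inter <- table(key)
    ij <- do.call(rbind, strsplit(names(inter), " ", fixed = TRUE))
    pairs <- tibble(
      pred = as.integer(ij[, 1]),
      gt = as.integer(ij[, 2]),
      inter = as.numeric(inter)
    )
    pairs$union <- psize[pairs$pred] + gsize[pairs$gt] - pairs$inter
    pairs$iou <- pairs$inter / pairs$union
  } else {
    pairs <- tibble(pred = integer(), gt = integer(), inter = numeric(),
                    union = numeric(), iou = numeric())
  }
  list(pairs = pairs,
       pred_labels = which(psize > 0),
       gt_labels = which(gsize > 0),
       psize = psize, gsize = gsize)
}

#' Voxel-wise binary accuracy
#'
#' Fraction of voxels whose binarised foreground/background status agrees.
#'
#' @param pred,gt Instance masks of identical shape.
#' @return A scalar in `[0, 1]`.
#' @export
voxel_accuracy <- function(pred, gt) {
  check_same_dims(pred, gt, "masks")
  mean((pred > 0) == (gt > 0))
}

#' One-to-one instance matching at an IoU threshold
#'
#' Greedy matching by descending IoU among candidate pairs with
#' `IoU >= iou_t`; each predicted and each ground-truth instance is used at
#' most once.
#'
#' @param pred,gt Instance masks of identical shape.
#' @param iou_t IoU threshold in `(0, 1]`.
#' @return An `instance_matching` object: a list with a `pairs` tibble
#'   (`pred`, `gt`, `iou`) and `unmatched_pred` / `unmatched_gt` label
#'   vectors.
#' @export
match_instances <- function(pred, gt, iou_t = 0.5) {
  check_same_dims(pred, gt, "masks")
  if (iou_t <= 0 || iou_t > 1) abort("iou_t must be in (0, 1]")
  ip <- iou_pairs(pred, gt)
  cand <- ip$pairs[ip$pairs$iou >= iou_t, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred, cand$gt), , drop = FALSE]
  used_p <- used_g <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$pred[i] %in% used_p) && !(cand$gt[i] %in% used_g)) {
      keep[i] <- TRUE
      used_p <- c(used_p, cand$pred[i])
      used_g <- c(used_g, cand$gt[i])
    }
  }
  pairs <- cand[keep, c("pred", "gt", "iou"), drop = FALSE]
  structure(list(
    pairs = as_tibble(pairs),
    unmatched_pred = setdiff(ip$pred_labels, pairs$pred),
    unmatched_gt = setdiff(ip$gt_labels, pairs$gt),
    iou_t = iou_t
  ), class = "instance_matching")
}

#' @export
print.instance_matching <- function(x, ...) {
  cat(sprintf("<instance_matching> %d matched pairs at IoU >= %.2f (%d FP, %d FN)\n",
              nrow(x$pairs), x$iou_t, length(x$unmatched_pred),
              length(x$unmatched_gt)))
  invisible(x)
}

#' @export
tidy.instance_matching <- function(x, ...) x$pairs

#' Instance-level precision, recall and F1
#'
#' @inheritParams match_instances
#' @return A one-row tibble with `precision`, `recall`, `f1` (a metric with a
#'   zero denominator is defined as 0).
#' @export
instance_prf <- function(pred, gt, iou_t = 0.5) {
  m <- match_instances(pred, gt, iou_t)
  tp <- nrow(m$pairs)
  fp <- length(m$unmatched_pred)
  fn <- length(m$unmatched_gt)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(precision = precision, recall = recall, f1 = f1)
}

#' Aggregated Jaccard index
#'
#' Ground-truth instances are matched one-to-one to predicted instances by
#' descending best IoU; AJI is the summed matched intersections over the
#' summed matched unions plus the areas of all unmatched predictions.
#'
#' @inheritParams voxel_accuracy
#' @return A scalar in `[0, 1]`.
#' @export
aji <- function(pred, gt) {
  check_same_dims(pred, gt, "masks")
  ip <- iou_pairs(pred, gt)
  if (length(ip$gt_labels) == 0) abort("ground truth has no instances")
  # per-GT best available prediction, processed in descending best-IoU order
  inter_sum <- 0
  union_sum <- 0
  used_p <- integer(0)
  pr <- ip$pairs
  gt_order <- ip$gt_labels
  best <- vapply(gt_order, function(g) {
    r <- pr[pr$gt == g, , drop = FALSE]
    if (nrow(r) == 0) 0 else max(r$iou)
  }, numeric(1))
  for (g in gt_order[order(-best)]) {
    r <- pr[pr$gt == g & !(pr$pred %in% used_p), , drop = FALSE]
    if (nrow(r) == 0) {
      union_sum <- union_sum + ip$gsize[g]
      next
    }
    r <- r[which.max(r$iou), ]
    inter_sum <- inter_sum + r$inter
    union_sum <- union_sum + r$union
    used_p <- c(used_p, r$pred)
  }
  unmatched_p <- setdiff(ip$pred_labels, used_p)
  union_sum <- union_sum + sum(ip$psize[unmatched_p])
  if (union_sum == 0) return(0)
  inter_sum / union_sum
}

#' Instance intersection-over-union (size-balanced)
#'
#' Mean over ground-truth cells of the IoU with their paired prediction.
#' Pairing uses best-IoU one-to-one matching at a permissive threshold (any
#' overlap counts); unmatched ground-truth cells contribute 0.  Every cell is
#' weighted equally regardless of its size.
#'
#' @inheritParams voxel_accuracy
#' @return A scalar in `[0, 1]`.
#' @export
iiou <- function(pred, gt) {
  check_same_dims(pred, gt, "masks")
  ip <- iou_pairs(pred, gt)
  M <- length(ip$gt_labels)
  if (M == 0) abort("ground truth has no instances")
  m <- match_instances_any(pred, gt)
  sum(m$iou) / M
}

# best-IoU one-to-one matching with threshold 0+ (any overlap)
match_instances_any <- function(pred, gt) {
  ip <- iou_pairs(pred, gt)
  cand <- ip$pairs[order(-ip$pairs$iou, ip$pairs$pred, ip$pairs$gt), ,
                   drop = FALSE]
  used_p <- used_g <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$pred[i] %in% used_p) && !(cand$gt[i] %in% used_g)) {
      keep[i] <- TRUE
      used_p <- c(used_p, cand$pred[i])
      used_g <- c(used_g, cand$gt[i])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Average precision at one or a range of IoU thresholds
#'
#' `AP@t = TP / (TP + FP + FN)` with instance matches defined by IoU `>= t`;
#' `ap_range()` averages the ten thresholds 0.50, 0.55, ..., 0.95.
#'
#' @inheritParams match_instances
#' @return A scalar in `[0, 1]`.
#' @export
ap_at <- function(pred, gt, iou_t = 0.5) {
  m <- match_instances(pred, gt, iou_t)
  tp <- nrow(m$pairs)
  denom <- tp + length(m$unmatched_pred) + length(m$unmatched_gt)
  if (denom == 0) return(0)
  tp / denom
}

#' @rdname ap_at
#' @export
ap_range <- function(pred, gt) {
  mean(vapply(seq(0.5, 0.95, by = 0.05), function(t) ap_at(pred, gt, t),
              numeric(1)))
}

#' Identity-aware recognition average precision
#'
#' A predicted instance counts as a true positive only if it matches a
#' ground-truth instance at `IoU >= iou_t` *and* carries that instance's
#' identity.  Predictions without an identity entry count as false positives.
#'
#' @inheritParams match_instances
#' @param pred_ids,gt_ids Tibbles/data frames with columns `label`
#'   (instance label) and `id` (identity string).
#' @return A scalar in `[0, 1]`.
#' @export
recognition_ap <- function(pred, gt, pred_ids, gt_ids, iou_t = 0.5) {
  m <- match_instances(pred, gt, iou_t)
  idmap <- function(ids) setNames(as.character(ids$id), as.character(ids$label))
  pm <- idmap(pred_ids); gm <- idmap(gt_ids)
  tp <- 0L
  if (nrow(m$pairs) > 0) {
    pid <- pm[as.character(m$pairs$pred)]
    gid <- gm[as.character(m$pairs$gt)]
    tp <- sum(!is.na(pid) & !is.na(gid) & pid == gid)
  }
  npred <- nrow(m$pairs) + length(m$unmatched_pred)
  ngt <- nrow(m$pairs) + length(m$unmatched_gt)
  denom <- tp + (npred - tp) + (ngt - tp)
  if (denom == 0) return(0)
  tp / denom
}

#' One-call segmentation evaluation report
#'
#' @inheritParams match_instances
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`,
#'   `aji`, `iiou`, `ap50`, `ap75`, `ap`.
#' @export
evaluate_segmentation <- function(pred, gt, iou_t = 0.5) {
  prf <- instance_prf(pred, gt, iou_t)
  tibble(
    accuracy = voxel_accuracy(pred, gt),
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    aji = aji(pred, gt),
    iiou = iiou(pred, gt),
    ap50 = ap_at(pred, gt, 0.5),
    ap75 = ap_at(pred, gt, 0.75),
    ap = ap_range(pred, gt)
  )
}
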