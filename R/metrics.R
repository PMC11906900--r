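# Training loss (combined soft Dice + cross-entropy) and evaluation metrics
# (hard Dice, 95th-percentile Hausdorff distance in physical units).

#' Softmax over the class axis
#'
#' @param logits array `(n_classes, H, W, D)`.
#' @return probability array of the same shape; per-voxel class sums are 1.
#' @export
softmax_probs <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1L])
  m <- exp(sweep(m, 2L, apply(m, 2L, max)))
  array(sweep(m, 2L, colSums(m), "/"), d)
}

check_prob_map <- function(p, g) {
  if (length(dim(p)) != 4L) stop("probability map must be (n_classes, H, W, D)")
  gv <- if (inherits(g, "label_map")) g$voxels else g
  if (!identical(as.integer(dim(p)[-1L]), as.integer(dim(gv))))
    stop("probability map and label shapes disagree")
  gv
}

#' Soft Dice loss
#'
#' Mean over the foreground classes (cortical, trabecular) of
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)` with the per-class
#' binarised ground truth; `eps = 1e-5` guards empty classes.
#'
#' @param p probability array `(n_classes, H, W, D)`.
#' @param g a [label_map()] or integer array.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(p, g, eps = 1e-5) {
  gv <- check_prob_map(p, g)
  K <- dim(p)[1L]
  per <- vapply(seq_len(K - 1L), function(cls) {
    pc <- p[cls + 1L, , , ]
    gc <- as.numeric(gv == cls)
    (2 * sum(pc * gc) + eps) / (sum(pc) + sum(gc) + eps)
  }, 1)
  1 - mean(per)
}

#' Cross-entropy loss
#'
#' Mean over voxels of `-log p` at the true class (the multi-class form of
#' the binary cross-entropy); probabilities are clamped away from zero.
#'
#' @param p probability array `(n_classes, H, W, D)`.
#' @param g a [label_map()] or integer array.
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(p, g, eps = 1e-12) {
  gv <- check_prob_map(p, g)
  K <- dim(p)[1L]
  m <- matrix(p, nrow = K)
  pt <- m[cbind(as.vector(gv) + 1L, seq_len(ncol(m)))]
  mean(-log(pmax(pt, eps)))
}

#' Combined segmentation loss
#'
#' `alpha * DiceLoss + beta * CrossEntropy`; the reference protocol uses
#' `alpha = beta = 0.5` to balance the two terms.
#'
#' @param p probability array `(n_classes, H, W, D)`.
#' @param g a [label_map()] or integer array.
#' @param alpha,beta term weights.
#' @return scalar loss.
#' @export
combined_loss <- function(p, g, alpha = 0.5, beta = 0.5) {
  alpha * dice_loss(p, g) + beta * cross_entropy_loss(p, g)
}

# node-level combined loss on token logits (n x K) for training
combined_loss_node <- function(logits, gv, alpha = 0.5, beta = 0.5, eps = 1e-5) {
  K <- ncol(val(logits))
  probs <- ad_softmax_rows(logits)
  gi <- as.integer(gv) + 1L
  total <- NULL
  for (cls in seq_len(K - 1L)) {
    pc <- ad_cols(probs, cls + 1L)
    gc <- matrix(as.numeric(gv == cls), ncol = 1L)
    pg <- ad_sum(ad_mul(pc, gc))
    psum <- ad_sum(pc)
    gsum <- sum(gc)
    dice <- ad_div(ad_add_const(ad_scale(pg, 2), eps),
                   ad_add_const(psum, gsum + eps))
    total <- if (is.null(total)) dice else ad_add(total, dice)
  }
  dice_l <- ad_add_const(ad_scale(total, -1 / (K - 1L)), 1)
  ce <- ad_scale(ad_mean(ad_log(ad_add_const(ad_pick(probs, gi), 1e-12))), -1)
  ad_add(ad_scale(dice_l, alpha), ad_scale(ce, beta))
}

#' Hard Dice score
#'
#' `2 |X intersect Y| / (|X| + |Y|)` on the class-`cls` binary masks. Both
#' masks empty gives 1 (perfect agreement on absence); exactly one empty
#' gives 0.
#'
#' @param pred,gt [label_map()]s (or integer arrays) of equal shape.
#' @param cls class to score (1 cortical, 2 trabecular).
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, gt, cls = 1L) {
  pv <- if (inherits(pred, "label_map")) pred$voxels else pred
  gv <- if (inherits(gt, "label_map")) gt$voxels else gt
  if (!identical(dim(pv), dim(gv))) stop("shapes disagree")
  a <- pv == cls
  b <- gv == cls
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

# boundary voxels: foreground with at least one 6-neighbour outside the mask
# (array borders count as outside)
boundary_mask <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift_and <- function(m, ax, dir) {
    s <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (n == 1L) return(s)
    if (dir > 0) { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    else { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    s[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    s
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_and(mask, ax, dir)
  mask & !interior
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary voxels (those with a 6-neighbour outside the mask) are extracted
#' from each class mask; Euclidean distances are measured between boundary
#' voxel centres in physical units (spacing-scaled). The default convention
#' is the maximum of the two directed 95th percentiles; `method = "pooled"`
#' instead takes the 95th percentile of both directed distance sets pooled.
#' Reported in millimetres (spacing is in micrometres).
#'
#' @param pred,gt [label_map()]s (or integer arrays) of equal shape.
#' @param cls class to score.
#' @param spacing voxel spacing in micrometres (taken from `pred` if it is a
#'   [label_map()]).
#' @param method `"max_directed"` (default) or `"pooled"`.
#' @return distance in mm; error if either class mask is empty (undefined).
#' @export
hd95 <- function(pred, gt, cls = 1L, spacing = NULL,
                 method = c("max_directed", "pooled")) {
  method <- match.arg(method)
  if (is.null(spacing))
    spacing <- if (inherits(pred, "label_map")) pred$spacing else c(1, 1, 1)
  pv <- if (inherits(pred, "label_map")) pred$voxels else pred
  gv <- if (inherits(gt, "label_map")) gt$voxels else gt
  if (!identical(dim(pv), dim(gv))) stop("shapes disagree")
  a <- pv == cls
  b <- gv == cls
  if (!any(a) || !any(b))
    stop(sprintf("HD95 undefined: empty class-%d mask", cls))
  ba <- boundary_mask(a)
  bb <- boundary_mask(b)
  da <- distance_transform(bb, spacing)[ba]   # pred boundary -> gt boundary
  db <- distance_transform(ba, spacing)[bb]   # gt boundary -> pred boundary
  v <- if (method == "pooled") stats::quantile(c(da, db), 0.95, names = FALSE)
       else max(stats::quantile(da, 0.95, names = FALSE),
                stats::quantile(db, 0.95, names = FALSE))
  v / 1000
}

#' Evaluate a predicted label map against ground truth
#'
#' Computes per-compartment Dice and HD95 (classes 1 and 2) plus their
#' means, mirroring the per-subset evaluation rows of the study protocol.
#'
#' @param pred,gt [label_map()]s of equal shape.
#' @param spacing voxel spacing in micrometres.
#' @param scan_id,subset bookkeeping labels for the output row.
#' @return a one-row `data.frame` (an evaluation record).
#' @export
evaluate_pair <- function(pred, gt, spacing = NULL, scan_id = "scan",
                          subset = NA_integer_) {
  if (is.null(spacing))
    spacing <- if (inherits(pred, "label_map")) pred$spacing else c(1, 1, 1)
  d1 <- dice_score(pred, gt, 1L)
  d2 <- dice_score(pred, gt, 2L)
  h1 <- tryCatch(hd95(pred, gt, 1L, spacing), error = function(e) NA_real_)
  h2 <- tryCatch(hd95(pred, gt, 2L, spacing), error = function(e) NA_real_)
  data.frame(scan_id = scan_id, subset = subset,
             dsc_avg = (d1 + d2) / 2, dsc_cortical = d1, dsc_trabecular = d2,
             hd95_avg = (h1 + h2) / 2, hd95_cortical = h1, hd95_trabecular = h2,
             stringsAsFactors = FALSE)
}

#' Evaluate a scan over z-subsets
#'
#' Splits prediction and ground truth into `n_subsets` slabs along z,
#' evaluates each slab, and appends two aggregate rows: `"mean"` (class-mean
#' per subset, then subset mean) and `"pooled"` (metrics on the whole
#' volume), since the aggregation order is a reporting choice.
#'
#' @param pred,gt [label_map()]s of equal shape.
#' @param spacing voxel spacing in micrometres.
#' @param n_subsets number of z-slabs (protocol: 10).
#' @param scan_id bookkeeping label.
#' @return a `data.frame` of evaluation records.
#' @export
evaluate_scan <- function(pred, gt, spacing = NULL, n_subsets = 10L,
                          scan_id = "scan") {
  if (is.null(spacing))
    spacing <- if (inherits(pred, "label_map")) pred$spacing else c(1, 1, 1)
  pv <- if (inherits(pred, "label_map")) pred else label_map(pred, spacing)
  gv <- if (inherits(gt, "label_map")) gt else label_map(gt, spacing)
  ivol <- intensity_volume(array(0, dim(pv$voxels)), spacing)
  subs_p <- split_z_subsets(ivol, pv, n_subsets)
  subs_g <- split_z_subsets(ivol, gv, n_subsets)
  rows <- lapply(seq_len(n_subsets), function(i)
    evaluate_pair(subs_p[[i]]$labels, subs_g[[i]]$labels, spacing, scan_id, i))
  tab <- do.call(rbind, rows)
  mean_row <- tab[1, ]
  mean_row$subset <- NA_integer_
  mean_row$scan_id <- paste0(scan_id, ":mean")
  for (cl in names(tab)[-(1:2)]) mean_row[[cl]] <- mean(tab[[cl]], na.rm = TRUE)
  pooled <- evaluate_pair(pv, gv, spacing, paste0(scan_id, ":pooled"))
  rbind(tab, mean_row, pooled)
}
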