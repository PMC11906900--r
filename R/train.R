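# Training loop (SGD + momentum, cosine annealing, live augmentation,
# random subvolume crops) and whole-volume sliding-window inference.

#' Scan-level train/validation/test split
#'
#' Splits at the scan level so all z-subsets of a scan stay together. Sizes
#' are `round(N * ratio)`, adjusted on the training set so they sum to `N`;
#' the assignment is a seeded permutation.
#'
#' @param scan_ids character or integer vector of scan identifiers.
#' @param ratios `(train, val, test)` fractions summing to one.
#' @param seed RNG seed.
#' @return `list(train, val, test)` of id vectors.
#' @export
make_splits <- function(scan_ids, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  N <- length(scan_ids)
  if (N < 3L) stop("need at least 3 scans to split")
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  sizes <- round(N * ratios)
  sizes[1L] <- sizes[1L] + (N - sum(sizes))
  if (any(sizes < 0L)) stop("degenerate split sizes")
  perm <- with_seed(seed, sample.int(N))
  ids <- scan_ids[perm]
  ends <- cumsum(sizes)
  list(train = ids[seq_len(sizes[1L])],
       val = if (sizes[2L] > 0) ids[(ends[1L] + 1L):ends[2L]] else scan_ids[0],
       test = if (sizes[3L] > 0) ids[(ends[2L] + 1L):ends[3L]] else scan_ids[0])
}

pad_to <- function(a, target, fill) {
  d <- dim(a)
  if (all(d >= target)) return(a)
  nd <- pmax(d, target)
  out <- array(fill, nd)
  lo <- (nd - d) %/% 2L
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- a
  out
}

#' Random training crop
#'
#' Crops image and labels identically to the given extents at a uniformly
#' random corner. Volumes smaller than the crop are first padded
#' symmetrically with background (image minimum, label 0).
#'
#' @param sample `list(image, labels)`.
#' @param crop target extents.
#' @param corner optional fixed 1-based corner (for reproducible runs).
#' @return the cropped sample.
#' @export
sample_crop <- function(sample, crop, corner = NULL) {
  crop <- as.integer(crop)
  img <- pad_to(sample$image$voxels, crop, min(sample$image$voxels))
  lab <- pad_to(sample$labels$voxels, crop, 0L)
  d <- dim(img)
  if (is.null(corner))
    corner <- vapply(1:3, function(i) sample.int(d[i] - crop[i] + 1L, 1L), 1L)
  ix <- lapply(1:3, function(i) corner[i] + seq_len(crop[i]) - 1L)
  list(image = intensity_volume(img[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
                                sample$image$spacing, sample$image$units),
       labels = label_map(lab[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
                          sample$labels$spacing))
}

#' Cosine annealing learning rate
#'
#' `lr(step) = 0.5 * lr0 * (1 + cos(pi * step / total_steps))`: starts at
#' `lr0`, halves at mid-schedule, reaches zero at the end.
#'
#' @param step current step (0-based).
#' @param total_steps schedule length.
#' @param lr0 initial learning rate.
#' @return the learning rate.
#' @export
cosine_lr <- function(step, total_steps, lr0 = 1e-4) {
  lr_min <- 0
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * step / total_steps))
}

# walk params/gradient trees in lockstep
tree_map2 <- function(a, b, f) {
  if (is.list(a) && !is_ad(a)) return(mapply(tree_map2, a, b,
                                             MoreArgs = list(f = f),
                                             SIMPLIFY = FALSE))
  f(a, b)
}

tree_grads <- function(nodes) {
  map_params(nodes, function(nd) {
    g <- nd$grad
    if (is.null(g)) array(0, dim(val(nd))) else g
  })
}

# foreground mean Dice of an argmax prediction on token logits
fg_mean_dice <- function(logits_mat, gv, K) {
  pred <- max.col(logits_mat, ties.method = "first") - 1L
  mean(vapply(seq_len(K - 1L), function(cls) {
    a <- pred == cls; b <- gv == cls
    if (sum(a) + sum(b) == 0L) return(1)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, 1))
}

#' Train a DBAHNet model
#'
#' SGD with momentum and cosine annealing on the combined Dice +
#' cross-entropy loss. Each step draws `batch_size` random crops from the
#' training samples, optionally augments them live, accumulates the
#' gradient, and updates. Training-crop foreground mean Dice is monitored
#' every `eval_every` steps; with `dsc_stop` set, training stops early once
#' it is reached. Fully reproducible from `config$seed`.
#'
#' @param model a [dbahnet()] model.
#' @param samples list of training samples `list(image, labels)` (z-scored
#'   images).
#' @param config a [train_config()].
#' @param augment an [augment_config()]; `p = 0` disables augmentation.
#' @param val_samples optional validation samples; validated by stitched
#'   sliding-window prediction every `steps_per_epoch` steps and the best
#'   weights retained.
#' @param fixed_crop use the deterministic corner `(1, 1, 1)` for every crop
#'   (reproducibility checks and single-crop overfitting).
#' @param eval_every monitoring cadence in steps.
#' @param dsc_stop optional early-stopping Dice target on the training crop.
#' @param verbose print a line per monitoring event.
#' @return an object of class `dbahnet_fit`: `list(model, state)` where
#'   `state` holds the step, loss trace, learning-rate trace, Dice history
#'   and best-validation bookkeeping.
#' @export
dbahnet_train <- function(model, samples, config = train_config(),
                          augment = augment_config(p = 0),
                          val_samples = NULL, fixed_crop = FALSE,
                          eval_every = 10L, dsc_stop = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dbahnet"), length(samples) >= 1L)
  cfg <- model$config
  K <- cfg$n_classes
  params <- model$params
  vel <- map_params(params, function(w) array(0, dim(w)))
  state <- list(step = 0L, loss = numeric(0), lr = numeric(0),
                train_dsc = numeric(0), train_dsc_step = integer(0),
                val_dsc = numeric(0), best_val = -Inf, seed = config$seed)
  best_params <- NULL
  set.seed(config$seed)
  crop <- config$crop
  # the deterministic crop is centred on the volume (bone-centred after
  # preprocessing)
  corner <- if (fixed_crop) {
    d0 <- pmax(dim(samples[[1L]]$image$voxels), crop)
    as.integer((d0 - crop) %/% 2L + 1L)
  } else NULL
  for (step in seq_len(config$max_steps)) {
    ad_reset_ids()   # graphs never outlive a step
    lr <- cosine_lr(step - 1L, config$max_steps, config$lr0)
    gacc <- NULL
    loss_acc <- 0
    for (bi in seq_len(config$batch_size)) {
      s <- samples[[if (length(samples) == 1L) 1L else sample.int(length(samples), 1L)]]
      s <- sample_crop(s, crop, corner = corner)
      if (augment$p > 0) s <- apply_augmentations(s, augment)
      nodes <- map_params(params, ad_var)
      g <- dbahnet_graph(matrix(as.vector(s$image$voxels), ncol = 1L),
                         crop, nodes, cfg)
      loss <- combined_loss_node(g$logits$x, as.vector(s$labels$voxels),
                                 config$loss_alpha, config$loss_beta)
      lv <- val(loss)[1L]
      if (!is.finite(lv))
        stop(sprintf("training diverged: non-finite loss at step %d", step))
      ad_backward(loss)
      gb <- tree_grads(nodes)
      gacc <- if (is.null(gacc)) gb else tree_map2(gacc, gb, `+`)
      loss_acc <- loss_acc + lv
    }
    if (config$batch_size > 1L)
      gacc <- map_params(gacc, function(g) g / config$batch_size)
    vel <- tree_map2(vel, gacc, function(v, g) config$momentum * v + g)
    params <- tree_map2(params, vel, function(w, v) w - lr * v)
    state$step <- step
    state$loss[step] <- loss_acc / config$batch_size
    state$lr[step] <- lr
    if (step %% eval_every == 0L || step == config$max_steps) {
      default_corner <- as.integer((pmax(dim(samples[[1L]]$image$voxels), crop) - crop) %/% 2L + 1L)
      s <- sample_crop(samples[[1L]], crop, corner = corner %||% default_corner)
      nodesv <- params  # plain arrays: forward only
      gv <- dbahnet_graph(matrix(as.vector(s$image$voxels), ncol = 1L),
                          crop, nodesv, cfg)
      dsc <- fg_mean_dice(val(gv$logits$x), as.vector(s$labels$voxels), K)
      state$train_dsc <- c(state$train_dsc, dsc)
      state$train_dsc_step <- c(state$train_dsc_step, step)
      if (verbose)
        message(sprintf("step %d: loss %.4f, lr %.2e, train-crop DSC %.4f",
                        step, state$loss[step], lr, dsc))
      if (!is.null(dsc_stop) && dsc >= dsc_stop) break
    }
    if (!is.null(val_samples) && step %% config$steps_per_epoch == 0L) {
      m_cur <- structure(list(config = cfg, params = params), class = "dbahnet")
      vd <- mean(vapply(val_samples, function(vs) {
        pr <- sliding_window_predict(m_cur, vs$image$voxels, window = crop)
        mean(c(dice_score(pr$voxels, vs$labels$voxels, 1L),
               dice_score(pr$voxels, vs$labels$voxels, 2L)))
      }, 1))
      state$val_dsc <- c(state$val_dsc, vd)
      if (vd > state$best_val) {
        state$best_val <- vd
        best_params <- params
      }
    }
  }
  final_params <- best_params %||% params
  out_model <- structure(list(config = cfg, params = final_params,
                              n_params = model$n_params,
                              init_seed = model$init_seed), class = "dbahnet")
  structure(list(model = out_model, state = state), class = "dbahnet_fit")
}

#' @export
print.dbahnet_fit <- function(x, ...) {
  st <- x$state
  cat(sprintf("DBAHNet fit: %d steps, final loss %.4f\n", st$step,
              st$loss[st$step]))
  if (length(st$train_dsc))
    cat(sprintf("  training-crop foreground mean DSC: %.4f\n",
                st$train_dsc[length(st$train_dsc)]))
  if (length(st$val_dsc))
    cat(sprintf("  best validation mean DSC: %.4f\n", st$best_val))
  invisible(x)
}

#' Sliding-window whole-volume prediction
#'
#' Tiles the volume with overlapping windows, blends softmax probabilities
#' with a separable Hann weight, and returns the voxel-wise argmax label
#' map. Volumes smaller than the window are padded with the volume minimum;
#' padded voxels are discarded.
#'
#' @param model a [dbahnet()] model.
#' @param vol 3D array or [intensity_volume()] (z-scored intensities).
#' @param window tile extents (must satisfy the embedding divisibility);
#'   default `E * 16`.
#' @param overlap fractional overlap between neighbouring tiles.
#' @return a [label_map()].
#' @export
sliding_window_predict <- function(model, vol, window = NULL, overlap = 0.5) {
  spacing <- c(1, 1, 1)
  if (inherits(vol, "intensity_volume")) {
    spacing <- vol$spacing
    vol <- vol$voxels
  }
  cfg <- model$config
  if (is.null(window)) window <- cfg$E * 16L
  window <- as.integer(window)
  check_embed_divisibility(cfg, window)
  d0 <- dim(vol)
  padded <- pad_to(vol, window, min(vol))
  d <- dim(padded)
  lo_off <- (d - d0) %/% 2L
  starts <- lapply(1:3, function(i) {
    if (d[i] == window[i]) return(1L)
    stride <- max(1L, as.integer(round(window[i] * (1 - overlap))))
    s <- seq.int(1L, d[i] - window[i] + 1L, by = stride)
    if (s[length(s)] != d[i] - window[i] + 1L) s <- c(s, d[i] - window[i] + 1L)
    s
  })
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)
  wgt <- outer(outer(hann(window[1]), hann(window[2])), hann(window[3])) + 1e-3
  K <- cfg$n_classes
  acc <- array(0, c(prod(d), K))
  wacc <- numeric(prod(d))
  tok_lin <- array(seq_len(prod(d)), d)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ad_reset_ids()
    ix <- sx:(sx + window[1] - 1L)
    iy <- sy:(sy + window[2] - 1L)
    iz <- sz:(sz + window[3] - 1L)
    tile <- padded[ix, iy, iz, drop = FALSE]
    g <- dbahnet_graph(matrix(as.vector(tile), ncol = 1L), window,
                       model$params, cfg)
    logit <- val(g$logits$x)
    m <- logit - apply(logit, 1L, max)
    pm <- exp(m) / rowSums(exp(m))
    lin <- as.vector(tok_lin[ix, iy, iz])
    wv <- as.vector(wgt)
    acc[lin, ] <- acc[lin, ] + pm * wv
    wacc[lin] <- wacc[lin] + wv
  }
  cls <- max.col(acc, ties.method = "first") - 1L
  lab <- array(as.integer(cls), d)
  lab <- lab[lo_off[1] + seq_len(d0[1]), lo_off[2] + seq_len(d0[2]),
             lo_off[3] + seq_len(d0[3]), drop = FALSE]
  label_map(lab, spacing = spacing)
}
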