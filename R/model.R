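# DBAHNet: dual-branch hybrid transformer/CNN encoder-decoder for 3-class
# segmentation of cortical and trabecular bone in 3D micro-CT volumes.
#
# Encoder levels run a shifted-window (Swin) transformer branch and a
# channel-attention convolution branch (CACM) in parallel, fused per level by
# a transformer-convolution feature fusion module (TCFFM). A four-block
# global-attention bottleneck links the mirrored decoder, whose convolution
# branch uses spatial attention (SACM) and whose skip connections pass
# through cross-attention gates. Feature maps internally are token matrices
# (see nn-ops.R); the public interface uses channel-first arrays (c, h, w, d).

#' Model architecture configuration
#'
#' Hyperparameter record for DBAHNet. Stage `s` of the hierarchy (s = 0..2,
#' plus the bottleneck as stage 3) carries `C * 2^s` channels; `heads[s + 1]`
#' attention heads operate at stage `s`, so every stage keeps the same head
#' dimension when heads double with channels.
#'
#' @param C embedding channels at stage 0 (reference model: 96).
#' @param E per-axis patch-embedding reduction factors, each 2 or 4
#'   (reference model: `c(4, 4, 2)`).
#' @param heads attention heads per stage, length 4 (reference: 6, 12, 24, 48).
#' @param depths number of Swin block pairs per hierarchy level, length 3.
#' @param window local-volume (window) extents for windowed attention.
#' @param mlp_ratio hidden expansion of the transformer MLPs.
#' @param n_classes output channels (background, cortical, trabecular).
#' @return an object of class `dbahnet_config`.
#' @export
dbahnet_config <- function(C = 96L, E = c(4L, 4L, 2L),
                           heads = c(6L, 12L, 24L, 48L),
                           depths = c(2L, 2L, 2L), window = c(4L, 4L, 2L),
                           mlp_ratio = 4L, n_classes = 3L) {
  C <- as.integer(C); E <- as.integer(E); heads <- as.integer(heads)
  depths <- as.integer(depths); window <- as.integer(window)
  if (length(E) != 3L || !all(E %in% c(2L, 4L)))
    stop("E must be a length-3 vector with components in {2, 4}")
  if (length(heads) != 4L) stop("heads must have length 4")
  if (C %% 2L != 0L) stop("C must be even")
  for (s in 0:3) {
    ch <- C * 2L^s
    if (ch %% heads[s + 1L] != 0L)
      stop(sprintf("stage %d channels (%d) not divisible by heads[%d] = %d",
                   s, ch, s + 1L, heads[s + 1L]))
  }
  if (length(depths) != 3L || any(depths < 1L)) stop("depths must be 3 positive counts")
  if (length(window) != 3L || any(window < 1L)) stop("window must be 3 positive extents")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  structure(list(C = C, E = E, heads = heads, depths = depths, window = window,
                 mlp_ratio = as.integer(mlp_ratio), n_classes = as.integer(n_classes)),
            class = "dbahnet_config")
}

#' @export
print.dbahnet_config <- function(x, ...) {
  cat("DBAHNet configuration\n")
  cat(sprintf("  C = %d, E = [%s], heads = [%s]\n", x$C,
              paste(x$E, collapse = ","), paste(x$heads, collapse = ",")))
  cat(sprintf("  depths = [%s], window = [%s], mlp_ratio = %d, classes = %d\n",
              paste(x$depths, collapse = ","), paste(x$window, collapse = ","),
              x$mlp_ratio, x$n_classes))
  invisible(x)
}

# per-axis strides of the two embedding convolutions: factor 4 -> (2, 2),
# factor 2 -> (2, 1)
embed_strides <- function(E) {
  s1 <- ifelse(E >= 2L, 2L, 1L)
  list(s1 = s1, s2 = as.integer(E %/% s1))
}

#' Stage shape ledger
#'
#' Channel and spatial extents of every stage of the network for a given
#' input shape: the patch embedding output, the three encoder fusion outputs,
#' and the bottleneck.
#'
#' @param config a [dbahnet_config()].
#' @param input_shape input volume extents `(H, W, D)`.
#' @return a list of named shape vectors `(channels, h, w, d)`.
#' @export
dbahnet_stage_shapes <- function(config, input_shape) {
  input_shape <- as.integer(input_shape)
  check_embed_divisibility(config, input_shape)
  sp <- input_shape %/% config$E
  out <- list(embedding = c(channels = config$C, h = sp[1], w = sp[2], d = sp[3]))
  for (s in 1:3) {
    sp2 <- sp %/% 2L^s
    nm <- if (s == 3) "bottleneck" else paste0("stage", s)
    out[[nm]] <- c(channels = config$C * 2L^s, h = sp2[1], w = sp2[2], d = sp2[3])
  }
  out
}

check_embed_divisibility <- function(config, input_shape) {
  need <- config$E * 8L
  if (any(input_shape %% need != 0L))
    stop(sprintf("input extents (%s) must be divisible by E*8 = (%s)",
                 paste(input_shape, collapse = ","), paste(need, collapse = ",")))
  invisible(TRUE)
}

## ---- parameter construction ----

build_embed <- function(b, cfg) {
  list(conv1 = init_conv(b, c(3, 3, 3), 1L, cfg$C %/% 2L),
       ln1 = init_ln(b, cfg$C %/% 2L),
       conv2 = init_conv(b, c(3, 3, 3), cfg$C %/% 2L, cfg$C),
       ln2 = init_ln(b, cfg$C))
}

build_swin <- function(b, cfg, ch, heads) {
  pairs <- vector("list", cfg$depths[1L])
  for (i in seq_along(pairs)) {
    pairs[[i]] <- list(reg = init_tlayer(b, ch, heads, cfg$window, cfg$mlp_ratio),
                       shf = init_tlayer(b, ch, heads, cfg$window, cfg$mlp_ratio))
  }
  pairs
}

build_cacm <- function(b, ch) {
  list(fc1 = init_linear(b, 2L * ch, ch %/% 2L),
       fc2 = init_linear(b, ch %/% 2L, ch),
       down = init_conv(b, c(3, 3, 3), ch, 2L * ch),
       ln = init_ln(b, 2L * ch))
}

build_sacm <- function(b, ch) {
  list(sp = init_linear(b, 2L, 1L),
       up = init_conv(b, c(2, 2, 2), ch, ch %/% 2L), # kernel = stride
       ln = init_ln(b, ch %/% 2L))
}

build_tcffm <- function(b, cfg, ch, heads) {
  list(fuse = init_linear(b, 2L * ch, ch),
       blk = init_tlayer(b, ch, heads, cfg$window, cfg$mlp_ratio))
}

# The gate starts as an identity skip: the value and output projections are
# initialised to the identity and the relative-position bias puts most of
# the softmax mass on the spatially aligned skip token, so full-resolution
# encoder content reaches the decoder (and the head) from the first
# optimisation step; training then sharpens or suppresses it.
build_gate <- function(b, cfg, ch, heads) {
  p <- list(ln1 = init_ln(b, ch),
            q = init_linear(b, ch, ch), k = init_linear(b, ch, ch),
            v = init_linear(b, ch, ch), o = init_linear(b, ch, ch),
            ln2 = init_ln(b, ch), mlp = init_mlp(b, ch, cfg$mlp_ratio))
  w <- cfg$window
  nrel <- prod(2L * w - 1L)
  p$relbias <- mk_par(b, c(nrel, heads), "zeros")
  if (b$materialize) {
    p$v$W <- p$v$W + diag(ch)
    p$o$W <- p$o$W + diag(ch)
    zero_off <- 1L + (w[1L] - 1L) +
      (2L * w[1L] - 1L) * ((w[2L] - 1L) + (2L * w[2L] - 1L) * (w[3L] - 1L))
    p$relbias[zero_off, ] <- 6
  }
  p
}

build_head <- function(b, cfg) {
  hc <- cfg$C %/% 2L
  st <- embed_strides(cfg$E)
  list(tconv1 = init_conv(b, st$s2, cfg$C, hc), ln1 = init_ln(b, hc),
       tconv2 = init_conv(b, st$s1, hc, hc), ln2 = init_ln(b, hc),
       out = init_linear(b, hc, cfg$n_classes))
}

dbahnet_build_params <- function(cfg, materialize = TRUE) {
  b <- new_builder(materialize)
  C <- cfg$C
  p <- list(embed = build_embed(b, cfg))
  for (s in 0:2) {
    ch <- C * 2L^s
    p[[paste0("enc", s)]] <- list(
      swin = build_swin(b, cfg, ch, cfg$heads[s + 1L]),
      trdown = c(init_conv(b, c(3, 3, 3), ch, 2L * ch), list(ln = init_ln(b, 2L * ch))),
      cacm = build_cacm(b, ch),
      tcffm = build_tcffm(b, cfg, 2L * ch, cfg$heads[s + 2L]))
  }
  p$bottleneck <- lapply(1:4, function(i) init_tlayer(b, 8L * C, cfg$heads[4L],
                                                      NULL, cfg$mlp_ratio))
  for (s in 2:0) {
    ch_in <- C * 2L^(s + 1L)
    ch <- C * 2L^s
    p[[paste0("dec", s)]] <- list(
      swin = build_swin(b, cfg, ch_in, cfg$heads[s + 2L]),
      trup = c(init_conv(b, c(2, 2, 2), ch_in, ch), list(ln = init_ln(b, ch))),
      sacm = build_sacm(b, ch_in),
      tcffm = build_tcffm(b, cfg, ch, cfg$heads[s + 1L]),
      gate = build_gate(b, cfg, ch, cfg$heads[s + 1L]))
  }
  p$head <- build_head(b, cfg)
  attr(p, "count") <- b$count
  p
}

#' Trainable parameter count
#'
#' Counts the trainable scalars of a configuration without allocating them.
#' The count scales approximately quadratically with the embedding dimension
#' `C`.
#'
#' @param config a [dbahnet_config()].
#' @return a single number.
#' @export
dbahnet_param_count <- function(config) {
  attr(dbahnet_build_params(config, materialize = FALSE), "count")
}

## ---- forward blocks (node level) ----

linear_fwd <- function(x, p) ad_add_bias(ad_matmul(x, p$W), p$b)

mlp_fwd <- function(x, p) linear_fwd(ad_gelu(linear_fwd(x, p$fc1)), p$fc2)

# multi-head attention over non-overlapping (optionally shifted) windows;
# kv = NULL for self-attention, otherwise a node supplying keys/values
# (cross-attention in the gates). window = NULL means one global window.
attn_fwd <- function(x, dims, p, heads, window, shifted = FALSE, kv = NULL,
                     collect = NULL) {
  ch <- ncol(val(x))
  if (ch %% heads != 0L) stop("heads does not divide channels")
  dk <- ch %/% heads
  q_full <- linear_fwd(x, p$q)
  src <- if (is.null(kv)) x else kv
  k_full <- linear_fwd(src, p$k)
  v_full <- linear_fwd(src, p$v)
  n_tok <- prod(dims)
  if (is.null(window)) {
    wp <- list(gather = seq_len(n_tok), win_size = n_tok, n_win = 1L,
               masks = list(NULL), n_tokens = n_tok)
    ridx <- NULL
  } else {
    window <- pmin(as.integer(window), as.integer(dims))
    # no shift along axes the window already covers (standard Swin rule)
    shift <- if (shifted) ifelse(window >= dims, 0L, window %/% 2L)
             else c(0L, 0L, 0L)
    wp <- window_partition(dims, window, as.integer(shift))
    ridx <- relpos_index(window)
  }
  rb <- if (!is.null(ridx)) p$relbias else NULL
  qkv <- ad_cbind(ad_cbind(q_full, k_full), v_full)
  rows_all <- wp$rows %||% list(seq_len(n_tok))
  outs <- lapply(seq_len(wp$n_win), function(w) {
    QKVw <- ad_gather_rows(qkv, rows_all[[w]])
    ad_window_mhsa(QKVw, heads, dk, relbias = rb, ridx = ridx,
                   mask = wp$masks[[w]], collect = collect)
  })
  merged <- if (wp$n_win == 1L && identical(as.integer(wp$gather), seq_len(n_tok)))
    outs[[1L]]
  else ad_scatter_rows(ad_rbind(outs), wp$gather, n_tok)
  linear_fwd(merged, p$o)
}

# one pre-norm transformer layer: x + MHSA(LN(x)); x + MLP(LN(x))
tlayer_fwd <- function(fm, p, heads, window, shifted = FALSE, collect = NULL) {
  x <- fm$x
  a <- attn_fwd(ad_layernorm(x, p$ln1$g, p$ln1$b), fm$dims, p$attn, heads,
                window, shifted, collect = collect)
  x <- ad_add(x, a)
  m <- mlp_fwd(ad_layernorm(x, p$ln2$g, p$ln2$b), p$mlp)
  fmap(ad_add(x, m), fm$dims)
}

# Swin block pair(s): regular-window layer then shifted-window layer, the
# four-line residual scheme, repeated `depth` times
swin_fwd <- function(fm, pairs, heads, window) {
  for (pr in pairs) {
    fm <- tlayer_fwd(fm, pr$reg, heads, window, shifted = FALSE)
    fm <- tlayer_fwd(fm, pr$shf, heads, window, shifted = TRUE)
  }
  fm
}

# convolutions are followed by instance normalisation + GeLU: per-channel
# statistics over space keep every token's relative (and, through the
# affine, absolute) intensity, which channel-wise layer norm would erase at
# small channel counts
conv_ln_gelu <- function(fm, p, stride, k = c(3L, 3L, 3L)) {
  fm <- nn_conv3d(fm, p$W, p$b, stride = stride, k = k)
  fmap(ad_gelu(ad_instancenorm(fm$x, p$ln$g, p$ln$b)), fm$dims)
}

tconv_ln_gelu <- function(fm, p, stride) {
  fm <- nn_tconv3d(fm, p$W, p$b, stride)
  fmap(ad_gelu(ad_instancenorm(fm$x, p$ln$g, p$ln$b)), fm$dims)
}

embed_fwd <- function(fm, p, cfg) {
  st <- embed_strides(cfg$E)
  fm <- nn_conv3d(fm, p$conv1$W, p$conv1$b, stride = st$s1)
  fm <- fmap(ad_gelu(ad_instancenorm(fm$x, p$ln1$g, p$ln1$b)), fm$dims)
  fm <- nn_conv3d(fm, p$conv2$W, p$conv2$b, stride = st$s2)
  fmap(ad_gelu(ad_instancenorm(fm$x, p$ln2$g, p$ln2$b)), fm$dims)
}

cacm_fwd <- function(fm, p) {
  x <- fm$x
  ch <- ncol(val(x))
  if (ch %% 2L != 0L) stop("CACM requires an even channel count")
  if (any(fm$dims %% 2L != 0L)) stop("CACM requires even spatial extents")
  desc <- ad_cbind(ad_mean_rows(x), ad_max_rows(x))        # 1 x 2C
  a <- ad_sigmoid(linear_fwd(ad_gelu(linear_fwd(desc, p$fc1)), p$fc2)) # 1 x C
  xm <- fmap(ad_scale_cols(x, a), fm$dims)
  conv_ln_gelu(xm, list(W = p$down$W, b = p$down$b, ln = p$ln), stride = c(2L, 2L, 2L))
}

sacm_fwd <- function(fm, p) {
  x <- fm$x
  ch <- ncol(val(x))
  if (ch %% 2L != 0L) stop("SACM requires an even channel count")
  desc <- ad_cbind(ad_max_cols(x), ad_mean_cols(x))        # n x 2
  a <- ad_sigmoid(linear_fwd(desc, p$sp))                  # n x 1
  xm <- fmap(ad_scale_rows(x, a), fm$dims)
  tconv_ln_gelu(xm, list(W = p$up$W, b = p$up$b, ln = p$ln), stride = c(2L, 2L, 2L))
}

tcffm_fwd <- function(tr, cv, p, heads, window) {
  if (!identical(dim(val(tr$x)), dim(val(cv$x))) || !identical(tr$dims, cv$dims))
    stop("TCFFM branch shapes disagree")
  tr2 <- ad_scale_cols(tr$x, ad_sigmoid(ad_mean_rows(tr$x)))
  cv2 <- ad_scale_cols(cv$x, ad_sigmoid(ad_mean_rows(cv$x)))
  fused <- linear_fwd(ad_cbind(tr2, cv2), p$fuse)
  tlayer_fwd(fmap(fused, tr$dims), p$blk, heads, window)
}

gate_fwd <- function(query, skip, p, heads, window) {
  if (!identical(query$dims, skip$dims)) stop("attention gate spatial mismatch")
  x <- query$x
  a <- attn_fwd(ad_layernorm(x, p$ln1$g, p$ln1$b), query$dims,
                list(q = p$q, k = p$k, v = p$v, o = p$o, relbias = p$relbias),
                heads, window, kv = skip$x)
  x <- ad_add(x, a)
  m <- mlp_fwd(ad_layernorm(x, p$ln2$g, p$ln2$b), p$mlp)
  fmap(ad_add(x, m), query$dims)
}

head_fwd <- function(fm, p, cfg) {
  st <- embed_strides(cfg$E)
  fm <- tconv_ln_gelu(fm, list(W = p$tconv1$W, b = p$tconv1$b, ln = p$ln1), st$s2)
  fm <- tconv_ln_gelu(fm, list(W = p$tconv2$W, b = p$tconv2$b, ln = p$ln2), st$s1)
  fmap(linear_fwd(fm$x, p$out), fm$dims)
}

# full network graph; params entries may be ad_var nodes (training) or plain
# arrays (inference). Returns list(logits_fm, stages).
dbahnet_graph <- function(vol_mat, dims, params, cfg) {
  w <- cfg$window
  e0 <- embed_fwd(fmap(vol_mat, dims), params$embed, cfg)
  stages <- list(embedding = c(ncol(val(e0$x)), e0$dims))
  skips <- list(e0)
  x <- e0
  for (s in 0:2) {
    pe <- params[[paste0("enc", s)]]
    hs <- cfg$heads[s + 1L]
    tr <- swin_fwd(x, pe$swin, hs, w)
    tr <- conv_ln_gelu(tr, pe$trdown, stride = c(2L, 2L, 2L))
    cv <- cacm_fwd(x, pe$cacm)
    x <- tcffm_fwd(tr, cv, pe$tcffm, cfg$heads[s + 2L], w)
    if (s < 2L) skips[[s + 2L]] <- x
  }
  stages$bottleneck <- c(ncol(val(x$x)), x$dims)
  for (blk in params$bottleneck)
    x <- tlayer_fwd(x, blk, cfg$heads[4L], window = NULL)
  for (s in 2:0) {
    pd <- params[[paste0("dec", s)]]
    tr <- swin_fwd(x, pd$swin, cfg$heads[s + 2L], w)
    tr <- tconv_ln_gelu(tr, pd$trup, stride = c(2L, 2L, 2L))
    cv <- sacm_fwd(x, pd$sacm)
    f <- tcffm_fwd(tr, cv, pd$tcffm, cfg$heads[s + 1L], w)
    x <- gate_fwd(f, skips[[s + 1L]], pd$gate, cfg$heads[s + 1L], w)
  }
  logits <- head_fwd(x, params$head, cfg)
  list(logits = logits, stages = stages)
}

## ---- array <-> token helpers ----

# channel-first array (c, h, w, d) -> tokens x channels matrix
arr_to_tokens <- function(a) {
  d <- dim(a)
  t(matrix(a, nrow = d[1L]))
}

tokens_to_arr <- function(m, dims) {
  array(t(m), c(ncol(m), dims))
}

## ---- the classed model object ----

#' Construct a DBAHNet model
#'
#' Allocates and initialises all trainable parameters for a configuration.
#' Linear and attention weights are drawn from a truncated normal (sd 0.02),
#' convolution kernels from a He-scaled normal; biases start at zero and
#' layer-norm gains at one.
#'
#' @param config a [dbahnet_config()].
#' @param seed integer seed for the initialisation draw.
#' @return an object of class `dbahnet`.
#' @seealso [dbahnet_train()], [predict.dbahnet()]
#' @export
dbahnet <- function(config = dbahnet_config(), seed = 1L) {
  params <- with_seed(seed, dbahnet_build_params(config, materialize = TRUE))
  structure(list(config = config, params = params,
                 n_params = attr(params, "count"), init_seed = as.integer(seed)),
            class = "dbahnet")
}

# run a seeded draw without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' @export
print.dbahnet <- function(x, ...) {
  cat("DBAHNet segmentation model\n")
  print(x$config)
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(x$n_params, big.mark = ","), x$n_params / 1e6))
  invisible(x)
}

#' @export
summary.dbahnet <- function(object, ...) {
  fl <- flatten_params(object$params)
  comp <- sub("\\..*$", "", names(fl))
  counts <- tapply(vapply(fl, length, 1L), comp, sum)
  out <- data.frame(component = names(counts), parameters = as.vector(counts))
  out <- out[order(-out$parameters), ]
  rownames(out) <- NULL
  cat("DBAHNet parameter budget by component\n")
  print(out)
  invisible(out)
}

#' @export
coef.dbahnet <- function(object, ...) flatten_params(object$params)

# flatten the nested parameter list into a named flat list of arrays
flatten_params <- function(p, prefix = NULL) {
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    key <- if (is.null(prefix)) nms[i] else paste(prefix, nms[i], sep = ".")
    if (is.list(p[[i]]) && !inherits(p[[i]], "par_shape"))
      out <- c(out, flatten_params(p[[i]], key))
    else out[[key]] <- p[[i]]
  }
  out
}

# map every numeric leaf of the parameter tree through f (used to wrap the
# tree in ad_var nodes and to apply optimiser updates)
map_params <- function(p, f) {
  if (is.list(p) && !is_ad(p)) return(lapply(p, map_params, f = f))
  f(p)
}

#' Full forward pass
#'
#' Runs the complete network on a single-channel volume and returns per-class
#' logits. The channel-wise softmax of the result sums to one at every voxel.
#'
#' @param vol a 3D array or [intensity_volume()]; extents must be divisible
#'   by `E * 8` per axis.
#' @param model a [dbahnet()] model (or pass `config`/`params` explicitly).
#' @return array of logits `(n_classes, H, W, D)`.
#' @export
dbahnet_forward <- function(vol, model) {
  if (inherits(vol, "intensity_volume")) vol <- vol$voxels
  dims <- dim(vol)
  check_embed_divisibility(model$config, dims)
  ad_reset_ids()
  g <- dbahnet_graph(matrix(as.vector(vol), ncol = 1L), as.integer(dims),
                     model$params, model$config)
  tokens_to_arr(val(g$logits$x), dims)
}

#' Segment a volume by sliding-window inference
#'
#' Tiles the volume with overlapping windows, blends the per-tile softmax
#' maps with a separable cosine (Hann) weight, and takes the voxel-wise
#' argmax. Volumes smaller than the window are padded with their minimum
#' intensity; padded voxels are discarded from the output.
#'
#' @param object a [dbahnet()] model.
#' @param newdata an [intensity_volume()] or 3D array (z-scored intensities).
#' @param window tile extents; defaults to `E * 8` times c(2, 2, 2).
#' @param overlap fractional tile overlap per axis (default 0.5).
#' @param ... unused.
#' @return a [label_map()] with the model's voxel classes.
#' @export
predict.dbahnet <- function(object, newdata, window = NULL, overlap = 0.5, ...) {
  spacing <- c(1, 1, 1)
  if (inherits(newdata, "intensity_volume")) {
    spacing <- newdata$spacing
    newdata <- newdata$voxels
  }
  pred <- sliding_window_predict(object, newdata, window = window, overlap = overlap)
  label_map(pred$voxels, spacing = spacing)
}

## ---- exported block-level operations ----
# These run one architecture block on a channel-first array with freshly
# initialised (seeded) weights unless `params` is supplied; they exist so the
# blocks can be probed and tested in isolation.

block_params <- function(builder_fun, seed) {
  with_seed(seed, {
    b <- new_builder(TRUE)
    builder_fun(b)
  })
}

#' Patch embedding
#'
#' Projects a single-channel volume to `C` channels through two strided
#' 3x3x3 convolutions (each followed by layer normalisation and GeLU) whose
#' per-axis stride product equals the reduction vector `E`.
#'
#' @param vol 3D array `(H, W, D)`, extents divisible by `E * 8`.
#' @param config a [dbahnet_config()].
#' @param params optional parameter list (as built inside [dbahnet()]).
#' @param seed seed for fresh weights when `params` is missing.
#' @return channel-first array `(C, H/E1, W/E2, D/E3)`.
#' @export
patch_embed <- function(vol, config = dbahnet_config(), params = NULL, seed = 1L) {
  dims <- dim(vol)
  check_embed_divisibility(config, dims)
  if (is.null(params)) params <- block_params(function(b) build_embed(b, config), seed)
  fm <- embed_fwd(fmap(matrix(as.vector(vol), ncol = 1L), dims), params, config)
  tokens_to_arr(val(fm$x), fm$dims)
}

#' Windowed multi-head self-attention
#'
#' Partitions the volume into non-overlapping local windows (the shifted
#' variant displaces the grid by half a window with a cyclic shift plus
#' attention masking) and applies per-window multi-head
#' `Softmax(Q K' / sqrt(d_k)) V`.
#'
#' @param x channel-first array `(C, h, w, d)`.
#' @param heads number of attention heads (must divide `C`).
#' @param window local window extents (clipped to the spatial extents).
#' @param shifted use the shifted window grid.
#' @param params optional attention parameters; fresh seeded weights otherwise.
#' @param seed seed for fresh weights.
#' @param return_weights also return the per-window softmax attention
#'   matrices (rows sum to one).
#' @return the output array, or a list `(out, weights)` if requested.
#' @export
windowed_attention <- function(x, heads, window, shifted = FALSE, params = NULL,
                               seed = 1L, return_weights = FALSE) {
  ch <- dim(x)[1L]
  dims <- dim(x)[-1L]
  if (ch %% heads != 0L) stop("heads does not divide channels")
  if (is.null(params)) {
    w <- as.integer(pmin(window, dims)); attr(w, "heads") <- heads
    params <- block_params(function(b) init_attn(b, ch, w), seed)
  }
  collect <- if (return_weights) new.env() else NULL
  if (return_weights) collect$weights <- list()
  out <- attn_fwd(arr_to_tokens(x), as.integer(dims), params, heads,
                  as.integer(window), shifted = shifted, collect = collect)
  res <- tokens_to_arr(val(out), dims)
  if (return_weights) list(out = res, weights = collect$weights) else res
}

#' Swin transformer block
#'
#' The four-line residual scheme: layer-norm, windowed attention, residual;
#' layer-norm, MLP, residual; then the same with the shifted window grid.
#' Shape-preserving.
#'
#' @param x channel-first array `(C, h, w, d)` for the given stage.
#' @param config a [dbahnet_config()].
#' @param stage hierarchy stage 0..3 (selects the head count).
#' @param params optional block-pair parameters.
#' @param seed seed for fresh weights.
#' @return array of the same shape as `x`.
#' @export
swin_block_pair <- function(x, config = dbahnet_config(), stage = 0L,
                            params = NULL, seed = 1L) {
  ch <- dim(x)[1L]
  dims <- as.integer(dim(x)[-1L])
  heads <- config$heads[stage + 1L]
  if (is.null(params))
    params <- block_params(function(b) {
      list(reg = init_tlayer(b, ch, heads, config$window, config$mlp_ratio),
           shf = init_tlayer(b, ch, heads, config$window, config$mlp_ratio))
    }, seed)
  fm <- fmap(arr_to_tokens(x), dims)
  fm <- tlayer_fwd(fm, params$reg, heads, config$window, shifted = FALSE)
  fm <- tlayer_fwd(fm, params$shf, heads, config$window, shifted = TRUE)
  tokens_to_arr(val(fm$x), dims)
}

#' Channel-attention convolution module (encoder branch)
#'
#' Global average and max pooling give two `C`-vectors, concatenated and sent
#' through a GeLU bottleneck to a sigmoid channel mask that reweights the
#' input; a strided 3x3x3 convolution then halves the spatial extents and
#' doubles the channels.
#'
#' @param x channel-first array `(C, h, w, d)`, `C` and extents even.
#' @param params optional parameters.
#' @param seed seed for fresh weights.
#' @param return_attention also return the channel attention vector.
#' @return array `(2C, h/2, w/2, d/2)` (or a list with the attention map).
#' @export
cacm_forward <- function(x, params = NULL, seed = 1L, return_attention = FALSE) {
  ch <- dim(x)[1L]
  dims <- as.integer(dim(x)[-1L])
  if (is.null(params)) params <- block_params(function(b) build_cacm(b, ch), seed)
  fm <- fmap(arr_to_tokens(x), dims)
  if (return_attention) {
    desc <- ad_cbind(ad_mean_rows(fm$x), ad_max_rows(fm$x))
    a <- ad_sigmoid(linear_fwd(ad_gelu(linear_fwd(desc, params$fc1)), params$fc2))
    out <- cacm_fwd(fm, params)
    return(list(out = tokens_to_arr(val(out$x), out$dims), attention = as.vector(val(a))))
  }
  out <- cacm_fwd(fm, params)
  tokens_to_arr(val(out$x), out$dims)
}

#' Spatial-attention convolution module (decoder branch)
#'
#' Channel-wise max and mean maps are concatenated, mixed to a single-channel
#' sigmoid spatial mask that reweights the input; a stride-2 transpose
#' convolution then doubles the spatial extents and halves the channels.
#'
#' @param x channel-first array `(C, h, w, d)`, `C` even.
#' @param params optional parameters.
#' @param seed seed for fresh weights.
#' @param return_attention also return the spatial attention map.
#' @return array `(C/2, 2h, 2w, 2d)` (or a list with the attention map).
#' @export
sacm_forward <- function(x, params = NULL, seed = 1L, return_attention = FALSE) {
  ch <- dim(x)[1L]
  dims <- as.integer(dim(x)[-1L])
  if (is.null(params)) params <- block_params(function(b) build_sacm(b, ch), seed)
  fm <- fmap(arr_to_tokens(x), dims)
  if (return_attention) {
    desc <- ad_cbind(ad_max_cols(fm$x), ad_mean_cols(fm$x))
    a <- ad_sigmoid(linear_fwd(desc, params$sp))
    out <- sacm_fwd(fm, params)
    return(list(out = tokens_to_arr(val(out$x), out$dims),
                attention = array(val(a), dims)))
  }
  out <- sacm_fwd(fm, params)
  tokens_to_arr(val(out$x), out$dims)
}

#' Transformer-convolution feature fusion module
#'
#' Each branch is reweighted by a sigmoid of its channel-wise average-pooled
#' descriptor, the two are concatenated, fused by a 1x1x1 convolution back to
#' the branch width, and refined by one local-volume transformer block.
#'
#' @param x_tr,x_c channel-first arrays of identical shape (transformer and
#'   convolution branch outputs, already resampled by their branches).
#' @param config a [dbahnet_config()].
#' @param stage hierarchy stage of the fused features (selects heads).
#' @param params optional parameters.
#' @param seed seed for fresh weights.
#' @return array of the same shape as the inputs.
#' @export
tcffm_fuse <- function(x_tr, x_c, config = dbahnet_config(), stage = 1L,
                       params = NULL, seed = 1L) {
  if (!identical(dim(x_tr), dim(x_c))) stop("TCFFM branch shapes disagree")
  ch <- dim(x_tr)[1L]
  dims <- as.integer(dim(x_tr)[-1L])
  heads <- config$heads[stage + 1L]
  if (is.null(params))
    params <- block_params(function(b) build_tcffm(b, config, ch, heads), seed)
  out <- tcffm_fwd(fmap(arr_to_tokens(x_tr), dims), fmap(arr_to_tokens(x_c), dims),
                   params, heads, config$window)
  tokens_to_arr(val(out$x), out$dims)
}

#' Global-attention bottleneck
#'
#' Four sequential transformer blocks attending over all spatial positions
#' (no windowing) at the `8C`-channel bottleneck.
#'
#' @param x channel-first array `(8C, h, w, d)`.
#' @param config a [dbahnet_config()].
#' @param params optional parameters (list of four blocks).
#' @param seed seed for fresh weights.
#' @return array of the same shape as `x`.
#' @export
bottleneck_forward <- function(x, config = dbahnet_config(), params = NULL, seed = 1L) {
  ch <- dim(x)[1L]
  dims <- as.integer(dim(x)[-1L])
  if (ch %% config$heads[4L] != 0L) stop("heads does not divide channels")
  if (is.null(params))
    params <- block_params(function(b)
      lapply(1:4, function(i) init_tlayer(b, ch, config$heads[4L], NULL,
                                          config$mlp_ratio)), seed)
  fm <- fmap(arr_to_tokens(x), dims)
  for (blk in params) fm <- tlayer_fwd(fm, blk, config$heads[4L], window = NULL)
  tokens_to_arr(val(fm$x), dims)
}

#' Attention-gated skip connection
#'
#' Skip (encoder) tokens are projected to keys and values, decoder tokens
#' form the queries, and one windowed cross-attention transformer block
#' filters the skip content. Output shape equals the query shape.
#'
#' @param query channel-first decoder feature array.
#' @param skip channel-first encoder feature array, same shape.
#' @param config a [dbahnet_config()].
#' @param stage hierarchy stage of the gate (selects heads).
#' @param params optional parameters.
#' @param seed seed for fresh weights.
#' @return array of the query's shape.
#' @export
attention_gate <- function(query, skip, config = dbahnet_config(), stage = 0L,
                           params = NULL, seed = 1L) {
  if (!identical(dim(query)[-1L], dim(skip)[-1L]))
    stop("attention gate spatial mismatch")
  ch <- dim(query)[1L]
  dims <- as.integer(dim(query)[-1L])
  heads <- config$heads[stage + 1L]
  if (is.null(params))
    params <- block_params(function(b) build_gate(b, config, ch, heads), seed)
  out <- gate_fwd(fmap(arr_to_tokens(query), dims), fmap(arr_to_tokens(skip), dims),
                  params, heads, config$window)
  tokens_to_arr(val(out$x), dims)
}

## ---- checkpoints ----

#' Save / load model checkpoints
#'
#' A checkpoint stores the weights together with the full configuration;
#' loading refuses a checkpoint whose configuration disagrees with the one
#' requested.
#'
#' @param model a [dbahnet()] model.
#' @param path file path.
#' @param config optional configuration the checkpoint must match.
#' @return `load_checkpoint` returns the model; `save_checkpoint` the path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dbahnet"))
  saveRDS(list(config = model$config, params = model$params,
               n_params = model$n_params, init_seed = model$init_seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config) && !identical(unclass(ck$config), unclass(config)))
    stop("checkpoint configuration disagrees with the requested configuration")
  structure(list(config = ck$config, params = ck$params, n_params = ck$n_params,
                 init_seed = ck$init_seed), class = "dbahnet")
}
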