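# Spatial neural-network primitives on token matrices.
#
# A feature map is carried as a list(x = <node or matrix, tokens x channels>,
# dims = c(h, w, d)) with tokens ordered by the column-major linear index of
# the (h, w, d) grid. 3D convolutions are evaluated as one gather + matmul per
# kernel offset so the heavy lifting stays in BLAS; index tables depend only
# on geometry and are memoised.

.idx_cache <- new.env(parent = emptyenv())

fmap <- function(x, dims) list(x = x, dims = as.integer(dims))

lin_index <- function(coords, dims) {
  # coords: matrix n x 3 of 0-based grid coordinates; returns 1-based linear
  1L + coords[, 1L] + dims[1L] * (coords[, 2L] + dims[2L] * coords[, 3L])
}

grid_coords <- function(dims) {
  # all 0-based coordinates in column-major order
  as.matrix(expand.grid(x = 0:(dims[1L] - 1L), y = 0:(dims[2L] - 1L),
                        z = 0:(dims[3L] - 1L)))
}

conv_out_dims <- function(dims, k, stride, pad) {
  as.integer((dims + 2L * pad - k) %/% stride + 1L)
}

# gather index (one integer vector per kernel offset, 0 = out of bounds)
conv_indices <- function(dims, k, stride, pad) {
  key <- paste(c("c", dims, k, stride, pad), collapse = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  od <- conv_out_dims(dims, k, stride, pad)
  oc <- grid_coords(od)
  offs <- grid_coords(k)
  idx <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    ic <- cbind(oc[, 1L] * stride[1L] - pad[1L] + offs[o, 1L],
                oc[, 2L] * stride[2L] - pad[2L] + offs[o, 2L],
                oc[, 3L] * stride[3L] - pad[3L] + offs[o, 3L])
    ok <- ic[, 1L] >= 0L & ic[, 1L] < dims[1L] &
          ic[, 2L] >= 0L & ic[, 2L] < dims[2L] &
          ic[, 3L] >= 0L & ic[, 3L] < dims[3L]
    v <- integer(nrow(ic))
    v[ok] <- lin_index(ic[ok, , drop = FALSE], dims)
    attr(v, "uidx") <- sort.int(unique.default(v))
    idx[[o]] <- v
  }
  out <- list(idx = idx, out_dims = od)
  .idx_cache[[key]] <- out
  out
}

# 3D convolution. W is an array (prod(k), cin, cout); b length cout.
nn_conv3d <- function(fm, W, b, stride = c(1L, 1L, 1L), k = c(3L, 3L, 3L),
                      pad = (k - 1L) %/% 2L) {
  ci <- conv_indices(fm$dims, as.integer(k), as.integer(stride), as.integer(pad))
  Wv <- val(W)
  acc <- NULL
  for (o in seq_along(ci$idx)) {
    Wo <- if (is_ad(W)) {
      # slice offset o of the weight array as a view node
      ad_node(matrix(Wv[o, , ], nrow = dim(Wv)[2L]), list(W), local({
        oo <- o
        function(g) {
          dW <- array(0, dim(Wv))
          dW[oo, , ] <- g
          list(dW)
        }
      }))
    } else matrix(Wv[o, , ], nrow = dim(Wv)[2L])
    term <- ad_matmul(ad_gather_rows(fm$x, ci$idx[[o]]), Wo)
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  fmap(ad_add_bias(acc, b), ci$out_dims)
}

# Non-overlapping transpose convolution: kernel extents equal the stride, so
# each output voxel receives exactly one contribution. W: (prod(stride), cin,
# cout); output dims = dims * stride.
nn_tconv3d <- function(fm, W, b, stride) {
  stride <- as.integer(stride)
  od <- fm$dims * stride
  key <- paste(c("t", fm$dims, stride), collapse = "_")
  phase_idx <- .idx_cache[[key]]
  if (is.null(phase_idx)) {
    ic <- grid_coords(fm$dims)
    offs <- grid_coords(stride)
    phase_idx <- lapply(seq_len(nrow(offs)), function(o) {
      oc <- cbind(ic[, 1L] * stride[1L] + offs[o, 1L],
                  ic[, 2L] * stride[2L] + offs[o, 2L],
                  ic[, 3L] * stride[3L] + offs[o, 3L])
      v <- lin_index(oc, od)
      attr(v, "uidx") <- sort.int(v)
      v
    })
    .idx_cache[[key]] <- phase_idx
  }
  Wv <- val(W)
  n_out <- prod(od)
  acc <- NULL
  for (o in seq_along(phase_idx)) {
    Wo <- if (is_ad(W)) {
      ad_node(matrix(Wv[o, , ], nrow = dim(Wv)[2L]), list(W), local({
        oo <- o
        function(g) {
          dW <- array(0, dim(Wv))
          dW[oo, , ] <- g
          list(dW)
        }
      }))
    } else matrix(Wv[o, , ], nrow = dim(Wv)[2L])
    term <- ad_scatter_rows(ad_matmul(fm$x, Wo), phase_idx[[o]], n_out)
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  fmap(ad_add_bias(acc, b), od)
}

# 1x1x1 convolution is a plain channel mixing matmul
nn_conv1 <- function(fm, W, b) fmap(ad_add_bias(ad_matmul(fm$x, W), b), fm$dims)

## ---- window partitioning ----

# Partition a (padded, optionally cyclically shifted) token grid into
# non-overlapping windows. Returns:
#   gather: index into the unpadded token grid, ordered window-by-window
#           (0 = padded position -> zero feature row);
#   scatter: for each window token, the unpadded destination index (0 = pad);
#   win_size, n_win;
#   masks: list of additive attention masks (win_size x win_size), one per
#          window, combining the cyclic-shift region rule with padding.
window_partition <- function(dims, window, shift = c(0L, 0L, 0L)) {
  dims <- as.integer(dims); window <- as.integer(window); shift <- as.integer(shift)
  key <- paste(c("w", dims, window, shift), collapse = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  pd <- as.integer(ceiling(dims / window) * window)
  gc_ <- grid_coords(pd)
  # cyclic shift on the padded grid, then map back into the original grid
  src <- cbind((gc_[, 1L] + shift[1L]) %% pd[1L],
               (gc_[, 2L] + shift[2L]) %% pd[2L],
               (gc_[, 3L] + shift[3L]) %% pd[3L])
  inb <- src[, 1L] < dims[1L] & src[, 2L] < dims[2L] & src[, 3L] < dims[3L]
  src_lin <- integer(nrow(src))
  src_lin[inb] <- lin_index(src[inb, , drop = FALSE], dims)
  # region ids for the shift mask: tokens from different pre-shift regions
  # must not attend to each other; padded tokens get their own id. Boundaries
  # live on the padded grid, where the cyclic wrap happens.
  rid <- integer(nrow(src))
  for (ax in 1:3) {
    a <- src[, ax]
    r <- integer(length(a))
    if (shift[ax] > 0L) {
      r[a >= (pd[ax] - window[ax])] <- 1L
      r[a >= (pd[ax] - shift[ax])] <- 2L
    }
    rid <- rid * 3L + r
  }
  rid[!inb] <- -1L
  # order tokens window-by-window
  wc <- cbind(gc_[, 1L] %/% window[1L], gc_[, 2L] %/% window[2L],
              gc_[, 3L] %/% window[3L])
  nw <- pd %/% window
  wid <- wc[, 1L] + nw[1L] * (wc[, 2L] + nw[2L] * wc[, 3L])
  within <- (gc_[, 1L] %% window[1L]) +
    window[1L] * ((gc_[, 2L] %% window[2L]) + window[2L] * (gc_[, 3L] %% window[3L]))
  ord <- order(wid, within)
  ws <- prod(window)
  n_win <- prod(nw)
  gather <- src_lin[ord]
  attr(gather, "uidx") <- sort.int(unique.default(gather))
  rid_o <- rid[ord]
  masks <- vector("list", n_win)
  for (wdx in seq_len(n_win)) {
    rr <- rid_o[((wdx - 1L) * ws + 1L):(wdx * ws)]
    if (length(unique(rr)) > 1L)   # assigning NULL would shrink the list
      masks[[wdx]] <- ifelse(outer(rr, rr, "!="), -1e9, 0)
  }
  rows <- vector("list", n_win)
  for (wdx in seq_len(n_win)) {
    rr <- gather[((wdx - 1L) * ws + 1L):(wdx * ws)]
    attr(rr, "uidx") <- sort.int(unique.default(rr))
    rows[[wdx]] <- rr
  }
  out <- list(gather = gather, rows = rows, win_size = ws, n_win = n_win,
              masks = masks, n_tokens = prod(dims))
  .idx_cache[[key]] <- out
  out
}

# relative position bias index for a window (win_size^2 values into the
# (2wx-1)(2wy-1)(2wz-1) table), shared across windows
relpos_index <- function(window) {
  window <- as.integer(window)
  key <- paste(c("r", window), collapse = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc_ <- grid_coords(window)
  nrel <- 2L * window - 1L
  d1 <- outer(gc_[, 1L], gc_[, 1L], "-") + window[1L] - 1L
  d2 <- outer(gc_[, 2L], gc_[, 2L], "-") + window[2L] - 1L
  d3 <- outer(gc_[, 3L], gc_[, 3L], "-") + window[3L] - 1L
  idx <- 1L + d1 + nrel[1L] * (d2 + nrel[2L] * d3)
  .idx_cache[[key]] <- idx
  idx
}

## ---- parameter initialisation ----

# Parameter construction runs through a builder so the same code path can
# either materialise arrays (training) or just count them (complexity checks).
new_builder <- function(materialize = TRUE) {
  b <- new.env(parent = emptyenv())
  b$materialize <- materialize
  b$count <- 0
  b
}

mk_par <- function(b, dims, init = c("trunc_normal", "zeros", "ones", "he"),
                   sd = 0.02) {
  init <- match.arg(init)
  b$count <- b$count + prod(dims)
  if (!b$materialize) return(structure(list(dims = dims), class = "par_shape"))
  n <- prod(dims)
  v <- switch(init,
    zeros = numeric(n),
    ones = rep(1, n),
    trunc_normal = {
      x <- stats::rnorm(n, 0, sd)
      while (any(bad <- abs(x) > 2 * sd)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
      x
    },
    he = stats::rnorm(n, 0, sqrt(2 / dims[length(dims) - 1L]))
  )
  if (length(dims) == 1L) matrix(v, nrow = 1L) else array(v, dims)
}

init_conv <- function(b, k, cin, cout) {
  kk <- prod(k)
  list(W = {
    b$count <- b$count + kk * cin * cout
    if (!b$materialize) structure(list(dims = c(kk, cin, cout)), class = "par_shape")
    else array(stats::rnorm(kk * cin * cout, 0, sqrt(2 / (kk * cin))),
               c(kk, cin, cout))
  },
  b = mk_par(b, cout, "zeros"))
}

init_linear <- function(b, cin, cout) {
  list(W = mk_par(b, c(cin, cout), "trunc_normal"), b = mk_par(b, cout, "zeros"))
}

init_ln <- function(b, ch) list(g = mk_par(b, ch, "ones"), b = mk_par(b, ch, "zeros"))

init_attn <- function(b, ch, window = NULL) {
  p <- list(q = init_linear(b, ch, ch), k = init_linear(b, ch, ch),
            v = init_linear(b, ch, ch), o = init_linear(b, ch, ch))
  if (!is.null(window)) {
    nrel <- prod(2L * as.integer(window) - 1L)
    p$relbias <- mk_par(b, c(nrel, attr(window, "heads") %||% 1L), "trunc_normal")
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

init_mlp <- function(b, ch, ratio) {
  list(fc1 = init_linear(b, ch, ch * ratio), fc2 = init_linear(b, ch * ratio, ch))
}

# one pre-norm transformer layer (attention + MLP)
init_tlayer <- function(b, ch, heads, window = NULL, ratio = 4L) {
  w <- window
  if (!is.null(w)) attr(w, "heads") <- heads
  list(ln1 = init_ln(b, ch), attn = init_attn(b, ch, w),
       ln2 = init_ln(b, ch), mlp = init_mlp(b, ch, ratio))
}
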