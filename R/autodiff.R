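# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor that flows through the network is a plain numeric matrix of
# shape (tokens x channels); a node is an environment holding the value, its
# parent nodes and a backward closure mapping the node's upstream gradient to
# gradients for each parent. Plain numeric matrices passed into ops are
# treated as constants. ad_backward() runs an iterative topological sweep so
# graph depth is not limited by R's recursion stack.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$n <- 0L

# Nodes are environments: reference semantics mean that storing a node in a
# list (or a list of nodes in another node's parents) never deep-duplicates
# the ancestry graph — R's duplicate() stops at environments.
ad_node <- function(value, parents = NULL, backward = NULL) {
  .ad_counter$n <- .ad_counter$n + 1L
  e <- new.env(parent = emptyenv())
  e$id <- .ad_counter$n
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  class(e) <- "ad_node"
  e
}

is_ad <- function(x) inherits(x, "ad_node")

# Reset the node id counter. Called at the start of each training step so
# the per-backward visited table stays small; safe because graphs never
# outlive a step.
ad_reset_ids <- function() {
  .ad_counter$n <- 0L
  invisible(NULL)
}

# leaf variable (parameters); constants can stay plain matrices
ad_var <- function(value) ad_node(value)

val <- function(x) if (inherits(x, "ad_node")) x$value else x

# Backward pass from a scalar (1x1) node. Accumulates into $grad of every
# reachable node (fresh per call since graphs are built per step); caller
# reads gradients off its ad_var leaves, e.g. via ad_grad_of().
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  # iterative DFS topological order (recursion would overflow on deep graphs)
  topo <- vector("list", 4096L)
  nt <- 0L
  seen <- logical(root$id)
  stack <- vector("list", 256L)
  stg <- integer(256L)
  stack[[1L]] <- root
  stg[1L] <- 1L
  ns <- 1L
  while (ns > 0L) {
    node <- stack[[ns]]
    if (stg[ns] == 1L) {
      if (seen[node$id]) { ns <- ns - 1L; next }
      seen[node$id] <- TRUE
      stg[ns] <- 2L
      for (p in node$parents) {
        if (inherits(p, "ad_node") && !seen[p$id]) {
          ns <- ns + 1L
          if (ns > length(stack)) {
            stack <- c(stack, vector("list", length(stack)))
            stg <- c(stg, integer(length(stg)))
          }
          stack[[ns]] <- p
          stg[ns] <- 1L
        }
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
      node$grad <- NULL
      ns <- ns - 1L
    }
  }
  root$grad <- matrix(1, 1, 1)
  for (i in seq(nt, 1L)) {
    node <- topo[[i]]
    g <- node$grad
    if (is.null(node$backward) || is.null(g)) next
    gs <- node$backward(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (inherits(p, "ad_node") && !is.null(gs[[j]]))
        p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

# gradient of a leaf after ad_backward (NULL if unreached)
ad_grad_of <- function(node) node$grad

## ---- elementwise / linear algebra ----

ad_matmul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av %*% bv, list(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

ad_add <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av + bv, list(a, b), function(g) list(g, g))
}

# x (n x c) + bias (length c), broadcast over rows
ad_add_bias <- function(x, b) {
  xv <- val(x); bv <- val(b)
  ad_node(sweep(xv, 2L, as.vector(bv), "+"), list(x, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

ad_mul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(x, s) { # s plain scalar constant
  xv <- val(x)
  ad_node(xv * s, list(x), function(g) list(g * s))
}

ad_add_const <- function(x, c) {
  xv <- val(x)
  ad_node(xv + c, list(x), function(g) list(g))
}

ad_div <- function(a, b) { # elementwise, same shape (used on 1x1 scalars)
  av <- val(a); bv <- val(b)
  y <- av / bv
  ad_node(y, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_log <- function(x) {
  xv <- val(x)
  ad_node(log(xv), list(x), function(g) list(g / xv))
}

## ---- activations / normalisation ----

ad_gelu <- function(x) {
  xv <- val(x)
  ph <- stats::pnorm(xv)
  ad_node(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

ad_sigmoid <- function(x) {
  xv <- val(x)
  y <- 1 / (1 + exp(-xv))
  ad_node(y, list(x), function(g) list(g * y * (1 - y)))
}

# row-wise softmax; `mask` is an optional constant matrix added to the logits
# (large negative entries suppress forbidden attention pairs)
ad_softmax_rows <- function(x, mask = NULL) {
  xv <- val(x)
  if (!is.null(mask)) xv <- xv + mask
  m <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - m)
  y <- e / rowSums(e)
  ad_node(y, list(x), function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# row-wise layer normalisation over channels with affine (gamma, beta length c)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- val(x); gv <- as.vector(val(gamma)); bv <- as.vector(val(beta))
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ad_node(y, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - t1 - xhat * t2) * inv
    dgamma <- matrix(colSums(g * xhat), nrow = 1L)
    dbeta <- matrix(colSums(g), nrow = 1L)
    list(dx, dgamma, dbeta)
  })
}

## ---- data movement ----

# scatter-add helper: rows of m grouped by idx (0 = dropped) summed into
# n_out rows; `uidx` is sort(unique(idx)), precomputed by the caller. All
# index vectors the network uses are injective on their non-zero part, so
# the common case is a plain indexed assignment.
scatter_sum <- function(m, idx, n_out, uidx) {
  out <- matrix(0, n_out, ncol(m))
  nz <- length(uidx) - (uidx[1L] == 0L)
  if (nz == sum(idx > 0L)) {         # injective: no accumulation needed
    keep <- idx > 0L
    out[idx[keep], ] <- m[keep, , drop = FALSE]
    return(out)
  }
  rs <- rowsum(m, idx, reorder = TRUE)  # rows follow sort(unique(idx))
  keep <- uidx > 0L
  out[uidx[keep], ] <- rs[keep, , drop = FALSE]
  out
}

# gather rows by integer index; idx == 0 yields a zero row (used for padding)
ad_gather_rows <- function(x, idx) {
  xv <- val(x)
  y <- xv[pmax(idx, 1L), , drop = FALSE]
  z <- idx == 0L
  if (any(z)) y[z, ] <- 0
  nin <- nrow(xv)
  uidx <- attr(idx, "uidx")
  if (is.null(uidx)) uidx <- sort.int(unique.default(idx))
  ad_node(y, list(x), function(g) list(scatter_sum(g, idx, nin, uidx)))
}

# scatter-add rows into n_out rows: y[j,] = sum_{i: idx[i]==j} x[i,]
ad_scatter_rows <- function(x, idx, n_out) {
  xv <- val(x)
  uidx <- attr(idx, "uidx")
  if (is.null(uidx)) uidx <- sort.int(unique.default(idx))
  y <- scatter_sum(xv, idx, n_out, uidx)
  ad_node(y, list(x), function(g) {
    dx <- g[pmax(idx, 1L), , drop = FALSE]
    z <- idx == 0L
    if (any(z)) dx[z, ] <- 0
    list(dx)
  })
}

ad_cols <- function(x, j) {
  xv <- val(x)
  nc <- ncol(xv)
  ad_node(xv[, j, drop = FALSE], list(x), function(g) {
    dx <- matrix(0, nrow(g), nc)
    dx[, j] <- g
    list(dx)
  })
}

ad_cbind <- function(a, b) {
  av <- val(a); bv <- val(b)
  na <- ncol(av)
  ad_node(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  vals <- lapply(nodes, val)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ad_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

## ---- reductions ----

ad_sum <- function(x) {
  xv <- val(x)
  ad_node(matrix(sum(xv), 1L, 1L), list(x), function(g) {
    list(matrix(g[1L], nrow(xv), ncol(xv)))
  })
}

ad_mean <- function(x) ad_scale(ad_sum(x), 1 / length(val(x)))

# column means -> 1 x c (global average pooling over tokens)
ad_mean_rows <- function(x) {
  xv <- val(x)
  n <- nrow(xv)
  ad_node(matrix(colMeans(xv), 1L), list(x), function(g) {
    list(matrix(rep(as.vector(g) / n, each = n), n))
  })
}

# column-wise max -> 1 x c (global max pooling over tokens)
ad_max_rows <- function(x) {
  xv <- val(x)
  am <- max.col(t(xv), ties.method = "first")
  y <- matrix(xv[cbind(am, seq_len(ncol(xv)))], 1L)
  ad_node(y, list(x), function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[cbind(am, seq_len(ncol(xv)))] <- as.vector(g)
    list(dx)
  })
}

# row means -> n x 1 (channel-wise average map)
ad_mean_cols <- function(x) {
  xv <- val(x)
  C <- ncol(xv)
  ad_node(matrix(rowMeans(xv), ncol = 1L), list(x), function(g) {
    list(matrix(rep(as.vector(g) / C, C), ncol = C))
  })
}

# row-wise max -> n x 1 (channel-wise max map)
ad_max_cols <- function(x) {
  xv <- val(x)
  am <- max.col(xv, ties.method = "first")
  y <- matrix(xv[cbind(seq_len(nrow(xv)), am)], ncol = 1L)
  ad_node(y, list(x), function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[cbind(seq_len(nrow(xv)), am)] <- as.vector(g)
    list(dx)
  })
}

# pick one entry per row: y[i] = x[i, j[i]] -> n x 1 (true-class probability)
ad_pick <- function(x, j) {
  xv <- val(x)
  n <- nrow(xv)
  ad_node(matrix(xv[cbind(seq_len(n), j)], ncol = 1L), list(x), function(g) {
    dx <- matrix(0, n, ncol(xv))
    dx[cbind(seq_len(n), j)] <- as.vector(g)
    list(dx)
  })
}

# broadcast multiply columns by a 1 x c node (channel attention)
ad_scale_cols <- function(x, m) {
  xv <- val(x); mv <- as.vector(val(m))
  ad_node(sweep(xv, 2L, mv, "*"), list(x, m), function(g) {
    list(sweep(g, 2L, mv, "*"), matrix(colSums(g * xv), nrow = 1L))
  })
}

# broadcast multiply rows by an n x 1 node (spatial attention)
ad_scale_rows <- function(x, m) {
  xv <- val(x); mv <- as.vector(val(m))
  ad_node(xv * mv, list(x, m), function(g) {
    list(g * mv, matrix(rowSums(g * xv), ncol = 1L))
  })
}

# y = a %*% t(b) without materialising the transpose as a node
ad_matmul_bt <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(tcrossprod(av, bv), list(a, b), function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

# free reshape (column-major), gradient reshaped back
ad_reshape <- function(x, nr, nc) {
  xv <- val(x)
  ad_node(matrix(as.vector(xv), nr, nc), list(x), function(g) {
    list(matrix(as.vector(g), nrow(xv), ncol(xv)))
  })
}

# Fused per-window multi-head self/cross attention with hand-written
# backward. QKV is a (win_size x 3ch) node (queries, keys, values already
# projected and gathered); relbias an optional (n_rel x heads) node indexed
# by ridx (win x win); mask an optional constant additive matrix. The fused
# node keeps the graph small: one node per window instead of eight per
# window and head.
ad_window_mhsa <- function(QKV, heads, dk, relbias = NULL, ridx = NULL,
                           mask = NULL, collect = NULL) {
  v <- val(QKV)
  ch <- ncol(v) %/% 3L
  ws <- nrow(v)
  rb <- if (is.null(relbias)) NULL else val(relbias)
  As <- vector("list", heads)
  out <- matrix(0, ws, ch)
  sc <- 1 / sqrt(dk)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(v[, cols, drop = FALSE], v[, ch + cols, drop = FALSE]) * sc
    if (!is.null(rb)) S <- S + matrix(rb[ridx, h], ws, ws)
    if (!is.null(mask)) S <- S + mask
    m <- S[cbind(seq_len(ws), max.col(S, ties.method = "first"))]
    e <- exp(S - m)
    A <- e / rowSums(e)
    if (!is.null(collect)) collect$weights[[length(collect$weights) + 1L]] <- A
    As[[h]] <- A
    out[, cols] <- A %*% v[, 2L * ch + cols, drop = FALSE]
  }
  parents <- if (is.null(relbias) || !is_ad(relbias)) list(QKV)
             else list(QKV, relbias)
  ad_node(out, parents, function(g) {
    dv <- matrix(0, ws, 3L * ch)
    drel <- if (!is.null(rb)) matrix(0, nrow(rb), ncol(rb)) else NULL
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- As[[h]]
      gO <- g[, cols, drop = FALSE]
      Vh <- v[, 2L * ch + cols, drop = FALSE]
      dA <- tcrossprod(gO, Vh)
      dv[, 2L * ch + cols] <- crossprod(A, gO)
      dS <- (dA - rowSums(dA * A)) * A
      if (!is.null(drel)) {
        acc <- rowsum(as.vector(dS), as.vector(ridx), reorder = TRUE)
        drel[as.integer(rownames(acc)), h] <-
          drel[as.integer(rownames(acc)), h] + acc[, 1L]
      }
      dv[, cols] <- (dS %*% v[, ch + cols, drop = FALSE]) * sc
      dv[, ch + cols] <- crossprod(dS, v[, cols, drop = FALSE]) * sc
    }
    if (length(parents) == 2L) list(dv, drel) else list(dv)
  })
}

# instance normalisation: per-channel statistics over tokens (spatial
# positions), affine per channel. Used after convolutions, where per-token
# layer norm would erase absolute intensity at small channel counts.
ad_instancenorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- val(x); gv <- as.vector(val(gamma)); bv <- as.vector(val(beta))
  n <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ad_node(y, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    t1 <- colMeans(dxhat)
    t2 <- colMeans(dxhat * xhat)
    # dx = (dxhat - mean_c(dxhat) - xhat * mean_c(dxhat * xhat)) * inv
    dx <- sweep(dxhat, 2L, t1)
    dx <- dx - sweep(xhat, 2L, t2, "*")
    dx <- sweep(dx, 2L, inv, "*")
    dgamma <- matrix(colSums(g * xhat), nrow = 1L)
    dbeta <- matrix(colSums(g), nrow = 1L)
    list(dx, dgamma, dbeta)
  })
}
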