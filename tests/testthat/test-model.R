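# Architecture contracts: the stage-shape ledger, each block's geometry,
# attention arithmetic against hand-evaluated oracles, and gradient flow.

test_that("stage shape ledger reproduces the printed architecture geometry", {
  cfg96 <- dbahnet_config(C = 96L, E = c(4L, 4L, 4L))
  sh <- dbahnet_stage_shapes(cfg96, c(320L, 320L, 32L))
  expect_equal(unname(sh$embedding), c(96, 80, 80, 8))
  expect_equal(unname(sh$bottleneck), c(768, 10, 10, 1))
  # z axis doubles when the depth reduction halves
  sh2 <- dbahnet_stage_shapes(dbahnet_config(C = 96L, E = c(4L, 4L, 2L)),
                              c(320L, 320L, 32L))
  expect_equal(unname(sh2$embedding), c(96, 80, 80, 16))
  expect_equal(unname(sh2$bottleneck), c(768, 10, 10, 2))
})

test_that("patch embedding produces (C, H/E, W/E, D/E) and rejects bad extents", {
  cfg <- tiny_config()
  out <- patch_embed(array(rnorm(32 * 32 * 16), c(32, 32, 16)), cfg, seed = 2)
  expect_equal(dim(out), c(4L, 8L, 8L, 8L))
  expect_true(all(is.finite(out)))
  expect_error(patch_embed(array(0, c(100, 100, 32)), dbahnet_config(C = 96L,
               E = c(4L, 4L, 4L))), "divisible")
})

test_that("windowed attention matches a hand-evaluated two-token toy", {
  # single window over the whole map, one head, d_k = 2: choose x = I so the
  # projections are exactly the hand-set Q, K, V matrices
  Q <- matrix(c(1, 0.5, -1, 2), 2, 2)
  K <- matrix(c(0.3, -0.2, 1.5, 0.4), 2, 2)
  V <- matrix(c(2, -1, 0, 3), 2, 2)
  params <- list(q = list(W = Q, b = matrix(0, 1, 2)),
                 k = list(W = K, b = matrix(0, 1, 2)),
                 v = list(W = V, b = matrix(0, 1, 2)),
                 o = list(W = diag(2), b = matrix(0, 1, 2)))
  x <- array(0, c(2, 1, 1, 2))   # 2 channels, 2 tokens along z; x tokens = I
  x[1, 1, 1, 1] <- 1
  x[2, 1, 1, 2] <- 1
  out <- windowed_attention(x, heads = 1L, window = c(1L, 1L, 2L),
                            params = params, return_weights = TRUE)
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expected <- A %*% V
  got <- t(matrix(out$out, nrow = 2))
  expect_equal(got, expected, tolerance = 1e-6)
  expect_equal(rowSums(out$weights[[1]]), c(1, 1), tolerance = 1e-6)
})

test_that("attention rows sum to one on random windowed maps", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  for (shifted in c(FALSE, TRUE)) {
    res <- windowed_attention(x, heads = 2L, window = c(4L, 4L, 2L),
                              shifted = shifted, return_weights = TRUE)
    for (A in res$weights)
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
  }
})

test_that("window partition + reverse is a bijection on in-bounds tokens", {
  for (case in list(list(d = c(8L, 8L, 8L), w = c(4L, 4L, 2L), s = c(0L, 0L, 0L)),
                    list(d = c(8L, 8L, 8L), w = c(4L, 4L, 2L), s = c(2L, 2L, 1L)),
                    list(d = c(6L, 6L, 5L), w = c(4L, 4L, 2L), s = c(2L, 2L, 1L)))) {
    wp <- dbahnet:::window_partition(case$d, case$w, case$s)
    nz <- wp$gather[wp$gather > 0L]
    expect_equal(sort(nz), seq_len(prod(case$d)))  # each token exactly once
  }
})

test_that("shifted and unshifted attention agree only in the degenerate single-window case", {
  set.seed(9)
  params_seed <- 4L
  x <- array(rnorm(4 * 8 * 8 * 4), c(4, 8, 8, 4))
  a <- windowed_attention(x, 1L, c(4L, 4L, 2L), shifted = FALSE, seed = params_seed)
  b <- windowed_attention(x, 1L, c(4L, 4L, 2L), shifted = TRUE, seed = params_seed)
  expect_gt(max(abs(a - b)), 1e-6)
  xs <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))   # window covers everything
  a2 <- windowed_attention(xs, 1L, c(4L, 4L, 2L), shifted = FALSE, seed = params_seed)
  b2 <- windowed_attention(xs, 1L, c(4L, 4L, 2L), shifted = TRUE, seed = params_seed)
  expect_equal(a2, b2, tolerance = 1e-10)
})

test_that("swin block pair preserves shape and reduces to the identity under zeroed projections", {
  cfg <- tiny_config()
  set.seed(11)
  x <- array(rnorm(4 * 8 * 8 * 4), c(4, 8, 8, 4))
  out <- swin_block_pair(x, cfg, stage = 0L, seed = 3)
  expect_equal(dim(out), dim(x))
  # zero the output projections of attention and MLP: both residual branches
  # contribute nothing and the pair is the identity
  params <- dbahnet:::block_params(function(b) {
    list(reg = dbahnet:::init_tlayer(b, 4L, 1L, cfg$window, cfg$mlp_ratio),
         shf = dbahnet:::init_tlayer(b, 4L, 1L, cfg$window, cfg$mlp_ratio))
  }, 3)
  for (nm in c("reg", "shf")) {
    params[[nm]]$attn$o$W[] <- 0
    params[[nm]]$mlp$fc2$W[] <- 0
  }
  out0 <- swin_block_pair(x, cfg, stage = 0L, params = params)
  expect_equal(out0, x, tolerance = 1e-12)
})

test_that("CACM halves space, doubles channels, and its channel attention is a sigmoid permutation-equivariant pooling", {
  set.seed(13)
  x <- array(rnorm(4 * 8 * 8 * 4), c(4, 8, 8, 4))
  res <- cacm_forward(x, seed = 5, return_attention = TRUE)
  expect_equal(dim(res$out), c(8L, 4L, 4L, 2L))
  expect_true(all(res$attention > 0 & res$attention < 1))
  # shape contract from the reference model: (96, 80, 80, 8) -> (192, 40, 40, 4)
  # is forced by channels x2, extents /2; assert the rule on this input
  expect_equal(dim(res$out)[1], 2L * dim(x)[1])
  expect_equal(dim(res$out)[-1], dim(x)[-1] %/% 2L)
  # permuting input channels permutes the pooled descriptors identically
  perm <- c(3L, 1L, 4L, 2L)
  xp <- x[perm, , , , drop = FALSE]
  pool <- function(a) {
    m <- t(matrix(a, nrow = dim(a)[1]))
    c(colMeans(m), apply(m, 2, max))
  }
  expect_equal(pool(xp), pool(x)[c(perm, 4L + perm)])
})

test_that("SACM doubles space, halves channels, and yields a spatially constant mask on constant input", {
  set.seed(17)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  res <- sacm_forward(x, seed = 6, return_attention = TRUE)
  expect_equal(dim(res$out), c(2L, 8L, 8L, 4L))
  expect_true(all(res$attention > 0 & res$attention < 1))
  xc <- array(rep(rnorm(4), times = 4 * 4 * 2), c(4, 4, 4, 2))  # constant over space
  rc <- sacm_forward(xc, seed = 6, return_attention = TRUE)
  expect_lt(diff(range(rc$attention)), 1e-12)
})

test_that("TCFFM fuses two branches, keeps the shape, and a zero branch contributes only bias", {
  cfg <- tiny_config()
  set.seed(19)
  a <- array(rnorm(8 * 4 * 4 * 4), c(8, 4, 4, 4))
  b <- array(rnorm(8 * 4 * 4 * 4), c(8, 4, 4, 4))
  out <- tcffm_fuse(a, b, cfg, stage = 1L, seed = 7)
  expect_equal(dim(out), dim(a))
  # with the convolution branch identically zero, the fusion is a function
  # of the transformer branch only: changing b away from zero changes the
  # output, but two different zero-branch calls agree exactly
  z <- array(0, dim(b))
  o1 <- tcffm_fuse(a, z, cfg, stage = 1L, seed = 7)
  o2 <- tcffm_fuse(a, z, cfg, stage = 1L, seed = 7)
  expect_identical(o1, o2)
  expect_gt(max(abs(out - o1)), 1e-8)
})

test_that("bottleneck is shape-preserving with the printed head arithmetic", {
  cfg <- dbahnet_config(C = 96L, E = c(4L, 4L, 4L))
  expect_equal(8L * cfg$C, 768L)
  expect_equal((8L * cfg$C) %/% cfg$heads[4], 16L)  # head dimension
  tiny <- tiny_config()
  x <- array(rnorm(32 * 2 * 2 * 2), c(32, 2, 2, 2))
  out <- bottleneck_forward(x, tiny, seed = 8)
  expect_equal(dim(out), dim(x))
})

test_that("attention gate: zero skip with zero biases gives zero attention before the residual", {
  set.seed(23)
  ch <- 4L
  q <- matrix(rnorm(8 * ch), 8, ch)
  p <- dbahnet:::block_params(function(b) dbahnet:::build_gate(b, tiny_config(), ch, 1L), 9)
  att <- dbahnet:::attn_fwd(dbahnet:::ad_var(q), c(2L, 2L, 2L),
                            list(q = p$q, k = p$k, v = p$v, o = p$o),
                            1L, c(4L, 4L, 2L), kv = matrix(0, 8, ch))
  expect_equal(max(abs(dbahnet:::val(att))), 0)
  # hand-evaluated cross-attention toy (2 tokens, d_k = 2)
  Q <- matrix(c(0.2, 1, -0.4, 0.8), 2, 2)
  K <- matrix(c(1, 0.1, -0.5, 0.7), 2, 2)
  V <- matrix(c(0.5, 2, 1, -1), 2, 2)
  skip <- matrix(c(1, 0, 0, 1), 2, 2)
  query <- matrix(c(1, 0, 0, 1), 2, 2)
  pars <- list(q = list(W = Q, b = matrix(0, 1, 2)),
               k = list(W = K, b = matrix(0, 1, 2)),
               v = list(W = V, b = matrix(0, 1, 2)),
               o = list(W = diag(2), b = matrix(0, 1, 2)))
  att2 <- dbahnet:::attn_fwd(query, c(1L, 1L, 2L), pars, 1L, c(1L, 1L, 2L),
                             kv = skip)
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(dbahnet:::val(att2), A %*% V, tolerance = 1e-8)
  # full gate keeps the query shape
  g <- attention_gate(array(rnorm(4 * 8 * 8 * 4), c(4, 8, 8, 4)),
                      array(rnorm(4 * 8 * 8 * 4), c(4, 8, 8, 4)),
                      tiny_config(), stage = 0L, seed = 10)
  expect_equal(dim(g), c(4L, 8L, 8L, 4L))
})

test_that("full forward yields finite logits whose softmax sums to one per voxel", {
  cfg <- tiny_config()
  m <- dbahnet(cfg, seed = 3)
  vol <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  lg <- dbahnet_forward(vol, m)
  expect_equal(dim(lg), c(3L, 32L, 32L, 16L))
  expect_true(all(is.finite(lg)))
  p <- softmax_probs(lg)
  expect_equal(range(apply(p, c(2, 3, 4), sum)), c(1, 1), tolerance = 1e-5)
})

test_that("parameter count scales approximately quadratically in C", {
  c96 <- dbahnet_param_count(dbahnet_config(C = 96L, E = c(4L, 4L, 4L)))
  c48 <- dbahnet_param_count(dbahnet_config(C = 48L, E = c(4L, 4L, 4L)))
  expect_gt(c96 / c48, 3.5)
  expect_lt(c96 / c48, 4.3)
  # the trend holds for the shallower depth reduction too
  r2 <- dbahnet_param_count(dbahnet_config(C = 96L, E = c(4L, 4L, 2L))) /
    dbahnet_param_count(dbahnet_config(C = 48L, E = c(4L, 4L, 2L)))
  expect_gt(r2, 3.5)
  expect_lt(r2, 4.3)
})

test_that("head-dimension divisibility is enforced at construction and in blocks", {
  expect_error(dbahnet_config(C = 96L, heads = c(5L, 12L, 24L, 48L)), "divisible")
  expect_error(windowed_attention(array(0, c(6, 4, 4, 2)), heads = 4L,
                                  window = c(4L, 4L, 2L)), "divide")
})

test_that("checkpoints round-trip and refuse a mismatched configuration", {
  cfg <- tiny_config()
  m <- dbahnet(cfg, seed = 1)
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f, config = cfg)
  expect_equal(coef(m2), coef(m))
  expect_error(load_checkpoint(f, config = overfit_config()), "disagrees")
  unlink(f)
})
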