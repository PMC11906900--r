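# Loss identities with closed forms, and Dice/HD95 against exhaustive
# brute-force oracles.

test_that("soft Dice loss matches hand evaluation on the binary toy and closed forms", {
  # toy: 4 voxels, prediction (1,1,0,0) for class 1, truth (1,0,1,0):
  # Dice = 2*1/(2+2) = 0.5, loss 0.5
  p <- array(0, c(2, 4, 1, 1))
  p[2, , 1, 1] <- c(1, 1, 0, 0)
  p[1, , 1, 1] <- 1 - p[2, , 1, 1]
  g <- array(c(1L, 0L, 1L, 0L), c(4, 1, 1))
  expect_equal(dice_loss(p, g), 0.5, tolerance = 1e-4)
  # perfect one-hot: loss limited only by the smoothing constant
  ph <- array(0, c(3, 4, 2, 2))
  gt <- array(sample(0:2, 16, TRUE), c(4, 2, 2))
  for (k in 0:2) ph[k + 1, , , ][gt == k] <- 1
  expect_lt(dice_loss(ph, gt), 2e-5)
  # uniform prediction: per-class closed form 1 - (2 phi / 3) / (1/3 + phi)
  pu <- array(1 / 3, c(3, 6, 6, 6))
  gu <- array(sample(0:2, 216, TRUE, prob = c(0.6, 0.25, 0.15)), c(6, 6, 6))
  expected <- 1 - mean(vapply(1:2, function(cl) {
    phi <- mean(gu == cl)
    (2 * phi / 3) / (1 / 3 + phi)
  }, 1))
  expect_equal(dice_loss(pu, gu), expected, tolerance = 1e-4)
})

test_that("cross-entropy is zero for perfect one-hot and ln 3 for uniform three-class prediction", {
  gt <- array(sample(0:2, 27, TRUE), c(3, 3, 3))
  ph <- array(0, c(3, 3, 3, 3))
  for (k in 0:2) ph[k + 1, , , ][gt == k] <- 1
  expect_lt(cross_entropy_loss(ph, gt), 1e-10)
  pu <- array(1 / 3, c(3, 3, 3, 3))
  expect_equal(cross_entropy_loss(pu, gt), log(3), tolerance = 1e-12)
  expect_error(cross_entropy_loss(pu, array(0L, c(2, 2, 2))), "disagree")
})

test_that("the combined loss composes its two parts with the configured weights", {
  p <- array(0, c(2, 4, 1, 1))
  p[2, , 1, 1] <- c(0.9, 0.8, 0.1, 0.2)
  p[1, , 1, 1] <- 1 - p[2, , 1, 1]
  g <- array(c(1L, 0L, 1L, 0L), c(4, 1, 1))
  expect_equal(combined_loss(p, g, 1, 0), dice_loss(p, g))
  expect_equal(combined_loss(p, g, 0, 1), cross_entropy_loss(p, g))
  expect_equal(combined_loss(p, g, 0.5, 0.5),
               0.5 * dice_loss(p, g) + 0.5 * cross_entropy_loss(p, g))
  expect_equal(combined_loss(p, g, 0, 0), 0)
})

test_that("the differentiable loss agrees with the numeric loss on random logits", {
  set.seed(31)
  n <- 60
  logits <- matrix(rnorm(3 * n), n, 3)
  gv <- sample(0:2, n, TRUE)
  node <- dbahnet:::combined_loss_node(dbahnet:::ad_var(logits), gv, 0.5, 0.5)
  probs_arr <- array(t(exp(logits) / rowSums(exp(logits))), c(3, n, 1, 1))
  expect_equal(dbahnet:::val(node)[1],
               combined_loss(probs_arr, array(gv, c(n, 1, 1)), 0.5, 0.5),
               tolerance = 1e-6)
})

test_that("hard Dice matches exhaustive voxel counting and its conventions", {
  set.seed(33)
  gt <- label_map(array(sample(0:2, 216, TRUE), c(6, 6, 6)))
  expect_equal(dice_score(gt, gt, 1L), 1)
  expect_equal(dice_score(gt, gt, 2L), 1)
  # disjoint nonempty masks
  a <- array(0L, c(4, 4, 4)); a[1:2, , ] <- 1L
  b <- array(0L, c(4, 4, 4)); b[3:4, , ] <- 1L
  expect_equal(dice_score(a, b, 1L), 0)
  # both-empty -> 1, one-empty -> 0
  z <- array(0L, c(4, 4, 4))
  expect_equal(dice_score(z, z, 2L), 1)
  expect_equal(dice_score(a, z, 1L), 0)
  # random masks vs brute force
  for (rep in 1:20) {
    x <- array(sample(0:2, 216, TRUE), c(6, 6, 6))
    y <- array(sample(0:2, 216, TRUE), c(6, 6, 6))
    for (cl in 1:2) {
      inter <- sum(x == cl & y == cl)
      expect_equal(dice_score(x, y, cl), 2 * inter / (sum(x == cl) + sum(y == cl)))
    }
  }
})

test_that("HD95 reproduces hand-computed geometries in physical units", {
  d <- c(9L, 5L, 5L)
  a <- array(0L, d); a[2, 3, 3] <- 1L
  b <- array(0L, d); b[5, 3, 3] <- 1L       # 3 voxels apart along x
  expect_equal(hd95(a, b, 1L, spacing = c(5, 5, 5)), 0.015)
  # unit cube vs the same cube shifted by one voxel
  ca <- array(0L, c(8, 8, 8)); ca[2:4, 2:4, 2:4] <- 1L
  cb <- array(0L, c(8, 8, 8)); cb[3:5, 2:4, 2:4] <- 1L
  expect_equal(hd95(ca, cb, 1L, spacing = c(5, 5, 5)), 0.005)
  expect_equal(hd95(ca, ca, 1L, spacing = c(5, 5, 5)), 0)
  expect_error(hd95(ca, array(0L, c(8, 8, 8)), 1L), "empty")
})

test_that("Dice is symmetric, HD95 is symmetric and scales linearly with spacing", {
  set.seed(35)
  x <- array(as.integer(runif(8^3) < 0.4), c(8, 8, 8))
  y <- array(as.integer(runif(8^3) < 0.4), c(8, 8, 8))
  expect_equal(dice_score(x, y, 1L), dice_score(y, x, 1L))
  h1 <- hd95(x, y, 1L, spacing = c(5, 5, 5))
  expect_equal(hd95(y, x, 1L, spacing = c(5, 5, 5)), h1)
  expect_equal(hd95(x, y, 1L, spacing = c(10, 10, 10)), 2 * h1, tolerance = 1e-12)
})

test_that("Dice and HD95 match the brute-force oracle on random 8^3 mask pairs", {
  set.seed(37)
  for (rep in 1:25) {
    x <- array(as.integer(runif(8^3) < runif(1, 0.2, 0.6)), c(8, 8, 8))
    y <- array(as.integer(runif(8^3) < runif(1, 0.2, 0.6)), c(8, 8, 8))
    if (!any(x == 1L) || !any(y == 1L)) next
    inter <- sum(x & y)
    expect_identical(dice_score(x, y, 1L), 2 * inter / (sum(x) + sum(y)))
    for (meth in c("max_directed", "pooled")) {
      expect_equal(hd95(x, y, 1L, spacing = c(5, 4, 3), method = meth),
                   bf_hd95(x == 1L, y == 1L, spacing = c(5, 4, 3), method = meth),
                   tolerance = 1e-9)
    }
  }
})

test_that("for hard one-hot predictions the soft Dice loss is one minus the mean hard Dice", {
  set.seed(39)
  gt <- array(sample(0:2, 216, TRUE), c(6, 6, 6))
  pr <- array(sample(0:2, 216, TRUE), c(6, 6, 6))
  ph <- array(0, c(3, 6, 6, 6))
  for (k in 0:2) ph[k + 1, , , ][pr == k] <- 1
  hard <- mean(c(dice_score(pr, gt, 1L), dice_score(pr, gt, 2L)))
  expect_equal(dice_loss(ph, gt), 1 - hard, tolerance = 1e-4)
})

test_that("evaluation records carry per-compartment metrics and honour their invariants", {
  ph <- small_phantom(seed = 13, noise_sigma = 0)
  gt <- ph$labels
  rec <- evaluate_pair(gt, gt, spacing = gt$spacing)
  expect_equal(rec$dsc_avg, 1)
  expect_equal(rec$hd95_avg, 0)
  # class-swapped prediction scores strictly worse
  swapped <- gt$voxels
  swapped[gt$voxels == 1L] <- 2L
  swapped[gt$voxels == 2L] <- 1L
  rec2 <- evaluate_pair(label_map(swapped, gt$spacing), gt, spacing = gt$spacing)
  expect_lt(rec2$dsc_avg, rec$dsc_avg)
  expect_true(all(c(rec$dsc_cortical, rec$dsc_trabecular) >= 0 &
                  c(rec$dsc_cortical, rec$dsc_trabecular) <= 1))
  tab <- evaluate_scan(gt, gt, spacing = gt$spacing, n_subsets = 4L)
  expect_equal(nrow(tab), 6L)  # 4 subsets + mean + pooled
  expect_true(all(tab$dsc_avg == 1))
})
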