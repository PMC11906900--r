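# Postprocessing: morphology against the brute-force ball oracle, exact
# conservation laws, and the end-to-end effect on degraded phantoms.

test_that("EDT-based ball morphology equals brute-force dilation/erosion", {
  set.seed(41)
  m <- array(runif(10 * 10 * 8) < 0.3, c(10, 10, 8))
  for (r in c(1, 2, 3)) {
    expect_identical(binary_dilate(m, r), bf_dilate(m, r))
    expect_identical(binary_erode(m, r), bf_erode(m, r))
  }
})

test_that("opening and closing are idempotent", {
  set.seed(43)
  m <- array(runif(12 * 12 * 8) < 0.4, c(12, 12, 8))
  o <- binary_open(m, 2)
  expect_identical(binary_open(o, 2), o)
  cl <- binary_close(m, 2)
  expect_identical(binary_close(cl, 2), cl)
})

test_that("noise removal keeps exactly the largest foreground component", {
  l <- array(0L, c(16, 16, 8))
  l[4:10, 4:10, 2:6] <- 1L            # main bone
  l[5:8, 5:8, 3:5] <- 2L
  l[14:15, 14:15, 2:3] <- 1L          # 8-voxel satellite
  out <- remove_noise_components(label_map(l))
  expect_equal(sum(out$voxels[14:15, 14:15, 2:3]), 0L)
  expect_equal(sum(out$voxels > 0), sum(l > 0) - 8L)
  # class identities preserved inside the kept component
  expect_identical(out$voxels[5:8, 5:8, 3:5], l[5:8, 5:8, 3:5])
  single <- label_map(array(rep(c(0L, 1L), c(4, 4)), c(2, 2, 2)))
  expect_identical(remove_noise_components(single)$voxels, single$voxels)
  expect_error(remove_noise_components(label_map(array(0L, c(2, 2, 2)))),
               "foreground")
})

test_that("endosteal smoothing relabels opened-away cortical voxels as trabecular, conserving the total", {
  # cortical slab with a thin spur; opening radius 3 removes the spur
  l <- array(0L, c(24, 24, 12))
  l[4:20, 4:10, 3:10] <- 1L           # thick slab, open-stable
  l[11:12, 11:14, 6] <- 1L            # 2-wide spur into the cavity
  lm <- label_map(l)
  cfg <- postprocess_config(opening_radius = 3L)
  out <- smooth_endosteal_transition(lm, cfg)
  before <- table(factor(l, 0:2))
  after <- table(factor(out$voxels, 0:2))
  expect_equal(sum(after[c("1", "2")]), sum(before[c("1", "2")]))  # conserved
  # the spur is exactly what the brute-force opening removes
  opened <- bf_dilate(bf_erode(l == 1L, 3), 3)
  moved <- (l == 1L) & !opened
  expect_true(any(moved))
  expect_identical(out$voxels == 2L, moved)
  # idempotence: applying the smoothing twice equals once
  expect_identical(smooth_endosteal_transition(out, cfg)$voxels, out$voxels)
  # an open-stable mask is untouched: a full-width slab 7 voxels thick (the
  # in-plane faces are protected by the field-of-view border rule)
  stable <- array(0L, c(16, 16, 10)); stable[, , 3:9] <- 1L
  expect_identical(smooth_endosteal_transition(label_map(stable), cfg)$voxels,
                   stable)
})

test_that("trabecular reconnection merges a 1-voxel gap, leaves a 5-voxel gap, and never touches cortical", {
  mk <- function(gap) {
    l <- array(0L, c(30, 9, 9))
    l[2:10, 3:5, 3:5] <- 2L                      # 3x3 rod
    l[(11 + gap):28, 3:5, 3:5] <- 2L             # second rod after `gap`
    label_map(l)
  }
  cfg <- postprocess_config(closing_radius = 1L)
  n_comp <- function(lm) {
    lab <- label_components(lm$voxels == 2L, 26L)
    attr(lab, "n_components")
  }
  g1 <- connect_trabeculae(mk(1L), cfg)
  expect_equal(n_comp(g1), 1L)
  # matches the brute-force closing with the same ball
  l1 <- mk(1L)$voxels
  bf_closed <- bf_erode(bf_dilate(l1 == 2L, 1), 1)
  expect_identical(g1$voxels == 2L, (l1 == 2L) | (bf_closed & l1 == 0L))
  g5 <- connect_trabeculae(mk(5L), cfg)
  expect_equal(n_comp(g5), 2L)
  # a rod adjacent to a cortical wall: no cortical voxel is relabelled and
  # trabecular voxels are never removed
  l <- mk(1L)$voxels
  l[, 6, ] <- 1L
  out <- connect_trabeculae(label_map(l), cfg)
  expect_identical(out$voxels == 1L, l == 1L)
  expect_true(all(out$voxels[l == 2L] == 2L))
})

test_that("the pipeline repairs satellites, spurs and cut trabeculae, improving Dice", {
  ph <- small_phantom(seed = 15, noise_sigma = 0)
  gt <- ph$labels
  corrupted <- gt$voxels
  corrupted[2:3, 2:3, 2:3] <- 1L                       # satellite island
  trab_idx <- which(corrupted == 2L)
  set.seed(16)
  corrupted[sample(trab_idx, length(trab_idx) %/% 10)] <- 0L  # cut trabeculae
  lm <- label_map(corrupted, gt$spacing)
  out <- postprocess_pipeline(lm, postprocess_config())
  before <- mean(c(dice_score(lm, gt, 1L), dice_score(lm, gt, 2L)))
  after <- mean(c(dice_score(out, gt, 1L), dice_score(out, gt, 2L)))
  expect_gt(after, before)
  # clean input: near-identity (< 0.1% voxels changed; full-size phantom so
  # surface discretisation is a small fraction of the volume)
  big <- generate_phantom(phantom_params(noise_sigma = 0, seed = 19))
  clean <- postprocess_pipeline(big$labels, postprocess_config())
  expect_lt(mean(clean$voxels != big$labels$voxels), 0.001)
  expect_error(postprocess_pipeline(label_map(array(0L, c(4, 4, 4)))), "foreground")
})

test_that("postprocessing improves noisy predictions across degraded anatomies within the 0.5% band", {
  # ground truth varies over treatment-like anatomies whose true structures
  # stay connected at the closing scale; predictions carry segmentation
  # defects (a satellite island and randomly dropped trabecular voxels)
  ph <- generate_phantom(phantom_params(noise_sigma = 0, seed = 17))
  for (mode in c("identity", "thin", "densify")) {
    deg <- degrade_phantom(ph$volume, ph$labels, mode, seed = 18)
    gt <- deg$labels
    noisy <- gt$voxels
    noisy[2:4, 2:4, 2:4] <- 1L
    set.seed(20)
    ti <- which(noisy == 2L)
    noisy[sample(ti, length(ti) %/% 12)] <- 0L
    pred <- label_map(noisy, gt$spacing)
    before <- mean(c(dice_score(pred, gt, 1L), dice_score(pred, gt, 2L)))
    out <- postprocess_pipeline(pred, postprocess_config())
    after <- mean(c(dice_score(out, gt, 1L), dice_score(out, gt, 2L)))
    expect_gt(after, before - 0.005)
    expect_gt(after, before)
  }
  # a sparsified lattice treated as a *prediction* of the intact phantom is
  # repaired by the reconnection step
  sp <- degrade_phantom(ph$volume, ph$labels, "sparsify", seed = 18)
  gt0 <- ph$labels
  before <- mean(c(dice_score(sp$labels, gt0, 1L), dice_score(sp$labels, gt0, 2L)))
  out <- postprocess_pipeline(sp$labels, postprocess_config())
  after <- mean(c(dice_score(out, gt0, 1L), dice_score(out, gt0, 2L)))
  expect_gt(after, before)
})
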