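# Preprocessing against exhaustive oracles: Otsu thresholding, connected
# components, fibula removal, cropping, z-scoring, and whole-pipeline bone
# recall on phantoms with known ground truth.

test_that("Otsu-with-margin equals the exhaustive 256-threshold argmax on bimodal volumes", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 10 * 10 * 8
    x <- c(rnorm(n / 2, 60, 12), rnorm(n / 2, 180, 12))
    vol <- intensity_volume(array(sample(x), c(10, 10, 8)))
    mask <- otsu_threshold_with_margin(vol, preprocess_config(margin = 5L))
    rng <- range(vol$voxels)
    u <- round((vol$voxels - rng[1]) / (rng[2] - rng[1]) * 255)
    expect_equal(attr(mask, "threshold"), bf_otsu(as.vector(u)))
    expect_equal(attr(mask, "threshold_applied"), attr(mask, "threshold") - 5L)
    expect_identical(unclass(mask)[seq_along(mask)],
                     as.vector(u >= attr(mask, "threshold") - 5L))
  }
})

test_that("margin 0 reproduces plain Otsu and foreground grows monotonically in the margin", {
  set.seed(22)
  vol <- intensity_volume(array(c(rnorm(400, 50, 15), rnorm(400, 200, 15)), c(10, 10, 8)))
  m0 <- otsu_threshold_with_margin(vol, preprocess_config(margin = 0L))
  expect_equal(attr(m0, "threshold_applied"), attr(m0, "threshold"))
  counts <- vapply(0:10, function(M)
    sum(otsu_threshold_with_margin(vol, preprocess_config(margin = M))), 1L)
  expect_true(all(diff(counts) >= 0))
  expect_error(otsu_threshold_with_margin(intensity_volume(array(1, c(4, 4, 4)))),
               "constant")
})

test_that("largest-component keeps exactly the biggest 26-connected blob, with a deterministic tie break", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:6, 2:5, 2:6] <- TRUE    # 100 voxels
  m[9:11, 8:11, 2:5] <- c(rep(TRUE, 48))  # 48 voxels, disconnected
  out <- keep_largest_component_3d(m)
  expect_equal(sum(out), 100L)
  bf <- bf_components(m)
  expect_equal(sort(unique(bf[out])), 1L)
  # idempotent and connected
  expect_identical(keep_largest_component_3d(out), out)
  lab2 <- label_components(out, 26L)
  expect_equal(attr(lab2, "n_components"), 1L)
  # tie: two 8-voxel cubes; the one with the smaller minimum linear index wins
  t2 <- array(FALSE, c(10, 10, 4))
  t2[2:3, 2:3, 2:3] <- TRUE
  t2[7:8, 7:8, 2:3] <- TRUE
  kept <- keep_largest_component_3d(t2)
  expect_equal(sum(kept), 8L)
  expect_true(kept[2, 2, 2])
  expect_false(kept[7, 7, 2])
  expect_error(keep_largest_component_3d(array(FALSE, c(3, 3, 3))), "foreground")
})

test_that("compiled component labelling agrees with the brute-force labeller on random masks", {
  set.seed(23)
  for (conn in c(6L, 26L)) {
    m <- array(runif(8 * 8 * 6) < 0.35, c(8, 8, 6))
    lab <- label_components(m, conn)
    bf <- bf_components(m, conn)
    # same partition: component ids may differ, memberships may not
    expect_equal(attr(lab, "n_components"), max(bf))
    expect_equal(length(unique(paste(lab[m], bf[m]))), max(bf))
  }
})

test_that("fibula removal deletes exactly the second-largest 2D component per slice", {
  m <- array(FALSE, c(40, 40, 3))
  m[5:29, 5:24, 1:3] <- TRUE              # tibia, 500 px per slice
  m[33:38, 5:14, 1:3] <- TRUE             # fibula, 60 px per slice
  m[33, 30:34, 2] <- TRUE                 # 5-px speck in slice 2 only
  out <- remove_fibula_per_slice(m)
  expect_equal(sum(out[, , 1]), 500L)                 # fibula gone
  expect_equal(sum(out[, , 3]), 500L)
  expect_equal(sum(out[, , 2]), 505L)                 # literal rule: the
  expect_true(all(out[33, 30:34, 2]))                 # 5-px speck survives
  expect_true(all(out <= m))
  # single-component slices untouched
  one <- array(FALSE, c(10, 10, 2))
  one[3:6, 3:6, ] <- TRUE
  expect_identical(remove_fibula_per_slice(one), one)
})

test_that("autocrop returns the margin-expanded bounding box with background suppressed", {
  set.seed(24)
  v <- array(rnorm(64^3, 10), c(64, 64, 64))
  m <- array(FALSE, c(64, 64, 64))
  m[10:20, 10:20, 10:20] <- TRUE
  out <- autocrop_to_bone(intensity_volume(v), m, preprocess_config(crop_margin = 2L))
  expect_equal(dim(out$volume$voxels), c(15L, 15L, 15L))
  expect_true(all(out$volume$voxels[!out$mask] == min(out$volume$voxels)))
  # full-volume mask: shape unchanged; margin larger than volume: clipped
  full <- array(TRUE, c(8, 8, 8))
  o2 <- autocrop_to_bone(intensity_volume(v[1:8, 1:8, 1:8]), full,
                         preprocess_config(crop_margin = 0L))
  expect_equal(dim(o2$volume$voxels), c(8L, 8L, 8L))
  o3 <- autocrop_to_bone(intensity_volume(v[1:8, 1:8, 1:8]), full,
                         preprocess_config(crop_margin = 100L))
  expect_equal(dim(o3$volume$voxels), c(8L, 8L, 8L))
})

test_that("z-scoring uses the population standard deviation and is idempotent", {
  v <- intensity_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  z <- zscore_normalize(v)
  expect_equal(as.vector(z$voxels), c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_equal(mean(z$voxels), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$voxels^2)), 1, tolerance = 1e-12)
  z2 <- zscore_normalize(z)
  expect_equal(z2$voxels, z$voxels, tolerance = 1e-12)
  expect_error(zscore_normalize(intensity_volume(array(2, c(3, 3, 3)))), "variance")
})

test_that("pipeline keeps all bone and removes fibula and holder on a noise-free phantom", {
  ph <- small_phantom(seed = 5, noise_sigma = 0)
  pp <- preprocess_pipeline(ph$volume)
  gt <- crop_labels_to_bbox(ph$labels, pp$bbox)
  bone <- gt$voxels > 0L
  expect_equal(sum(pp$mask & bone) / sum(bone), 1)        # 100% recall
  # everything the mask keeps is true bone: fibula/holder rendered in
  # intensity but labelled background must be gone
  expect_equal(sum(pp$mask & !bone), 0L)
  expect_equal(pp$volume$units, "z-scored")
  expect_true(all(diff(pp$log) <= 0))                     # stages only remove
})

test_that("pipeline bone recall stays above 99% under scan noise", {
  rec <- vapply(1:3, function(seed) {
    ph <- small_phantom(seed = seed)     # default noise sd
    pp <- preprocess_pipeline(ph$volume)
    gt <- crop_labels_to_bbox(ph$labels, pp$bbox)
    bone <- gt$voxels > 0L
    sum(pp$mask & bone) / sum(bone)
  }, 1)
  expect_true(all(rec >= 0.99))
})

test_that("an all-background phantom fails at the threshold/empty-mask stage", {
  flat <- intensity_volume(array(rnorm(16^3, 0, 1e-8) + 5, c(16, 16, 16)))
  expect_error(preprocess_pipeline(intensity_volume(array(5, c(8, 8, 8)))),
               "constant")
  expect_true(is.list(tryCatch(preprocess_pipeline(flat), error = function(e) list())))
})
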