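# Synthetic tibia phantoms: an intensity volume that looks like a cropped
# micro-CT scan of a mouse tibia shaft plus exact ground-truth labels. The
# geometry emulates what the segmentation pipeline must cope with: a hollow,
# roughly cylindrical cortical shell; a sparse connected trabecular lattice
# in the medullary cavity; a fibula cross-section rendered in intensity but
# labelled background (preprocessing, not the generator, must remove it); a
# low-intensity holder/resin slab; and additive Gaussian noise.

#' Phantom parameters
#'
#' Defaults model a 5 um-resolution shaft region: cortical outer/inner radii
#' of 30/20 voxels (a 10-voxel, ~50 um cortex, comfortably thicker than the
#' postprocessing opening's support) with a mild proximal-to-distal taper, a trabecular volume
#' fraction of 0.25 inside the cavity with anisotropic field correlation
#' lengths (2.5, 2.5, 5) voxels — rod-like trabeculae ~25 um across aligned
#' with the load (z) axis, physiological for mice — and intensity means
#' ordered
#' cortical > trabecular > marrow > resin > air on an arbitrary [0, 1]
#' attenuation scale with noise sd 0.05 (contrast-to-noise ~ 8 for
#' trabecular bone over marrow, typical of high-resolution scans).
#'
#' @param shape volume extents `(H, W, D)`.
#' @param spacing voxel spacing in micrometres.
#' @param outer_radius,inner_radius cortical shell radii (voxels).
#' @param taper fractional linear radius reduction from first to last slice.
#' @param trab_fraction target trabecular volume fraction inside the cavity.
#' @param trab_scale per-axis Gaussian correlation lengths of the
#'   trabecular random field (voxels); set trabecular thickness and
#'   orientation.
#' @param fibula_radius,fibula_offset fibula cylinder radius and (x, y)
#'   offset from the tibia centre (voxels).
#' @param holder_width thickness of the holder/resin slab along x (voxels);
#'   0 disables it.
#' @param intensities named means: cortical, trabecular, marrow, resin, air.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed RNG seed; the same parameters always give the same phantom.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(96L, 96L, 48L), spacing = c(5, 5, 5),
                           outer_radius = 30, inner_radius = 20, taper = 0.05,
                           trab_fraction = 0.25, trab_scale = c(2.5, 2.5, 5),
                           fibula_radius = 14, fibula_offset = c(47, 0),
                           holder_width = 6L,
                           intensities = c(cortical = 0.85, trabecular = 0.65,
                                           marrow = 0.22, resin = 0.15,
                                           air = 0.02),
                           noise_sigma = 0.05, seed = 1L) {
  shape <- as.integer(shape)
  if (!(inner_radius < outer_radius && outer_radius < min(shape[1:2]) / 2))
    stop("need inner_radius < outer_radius < min(H, W) / 2")
  if (trab_fraction < 0 || trab_fraction >= 1)
    stop("trab_fraction must be in [0, 1)")
  need <- c("cortical", "trabecular", "marrow", "resin", "air")
  if (!all(need %in% names(intensities))) stop("missing intensity means")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 taper = taper, trab_fraction = trab_fraction,
                 trab_scale = trab_scale, fibula_radius = fibula_radius,
                 fibula_offset = fibula_offset, holder_width = as.integer(holder_width),
                 intensities = intensities[need], noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# separable Gaussian smoothing of a 3D array (dense kernel matrices per axis;
# axis lengths here are small enough that one BLAS multiply per axis wins)
gaussian_smooth_3d <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  if (all(sigma <= 0)) return(a)
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    n <- d[ax]
    K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma[ax]^2))
    K <- K / rowSums(K)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    back <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(2, 3, 1))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(K %*% matrix(ap, n), dp)
    a <- aperm(ap, back)
  }
  a
}

#' Generate a synthetic tibia phantom
#'
#' @param params a [phantom_params()].
#' @return `list(volume, labels)`: an [intensity_volume()] and the exact
#'   [label_map()] (fibula and holder are intensity-only, labelled 0).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, generate_phantom_impl(params))
}

generate_phantom_impl <- function(p) {
  d <- p$shape
  ints <- p$intensities
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  # shift the tibia towards the opposite face when a wide fibula would not
  # fit next to it; drop the fibula entirely if no shift can make room
  if (p$fibula_radius > 0) {
    over <- cx + p$fibula_offset[1] + p$fibula_radius + 1 - d[1]
    if (over > 0) {
      if (cx - over < p$outer_radius + 2) {
        warning("volume too small for the requested fibula; omitting it")
        p$fibula_radius <- 0
      } else cx <- cx - over
    }
  }
  r2 <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, "+")
  labels <- array(0L, d)
  vol <- array(ints["air"], d)
  cavity <- array(FALSE, d)
  zfrac <- if (d[3] > 1) (seq_len(d[3]) - 1) / (d[3] - 1) else 0
  for (z in seq_len(d[3])) {
    shrink <- 1 - p$taper * zfrac[z]
    Ro <- p$outer_radius * shrink
    Ri <- p$inner_radius * shrink
    shell <- r2 <= Ro^2 & r2 > Ri^2
    cav <- r2 <= Ri^2
    labels[, , z][shell] <- 1L
    vol[, , z][shell] <- ints["cortical"]
    vol[, , z][cav] <- ints["marrow"]
    cavity[, , z] <- cav
  }
  # trabecular lattice: thresholded smoothed Gaussian random field in the
  # cavity, then a radius-1 closing (confined to the cavity) to connect it;
  # isolated islands not attached to the cortical shell are dropped — bone
  # fragments floating in marrow do not exist anatomically
  if (p$trab_fraction > 0 && any(cavity)) {
    g <- gaussian_smooth_3d(array(stats::rnorm(prod(d)), d), p$trab_scale)
    thr <- stats::quantile(g[cavity], 1 - p$trab_fraction, names = FALSE)
    trab <- cavity & g >= thr
    trab <- binary_close(trab, 1) & cavity
    comp <- label_components(trab | labels == 1L, 26L)
    main <- comp[which(labels == 1L)[1L]]
    trab <- trab & comp == main
    labels[trab] <- 2L
    vol[trab] <- ints["trabecular"]
  }
  # fibula: a second bone rendered at cortical intensity but NOT labelled.
  # In-plane it is always a separate 2D component (the second-largest, which
  # the fibula-removal stage deletes), but in 3D it is diagonally connected
  # to the tibia through a two-voxel mineralised ridge spanning adjacent
  # slices — as in real scans, where the largest-component cleanup must keep
  # the fibula and the per-slice rule must remove it.
  if (p$fibula_radius > 0) {
    fx <- cx + p$fibula_offset[1]
    fy <- cy + p$fibula_offset[2]
    fib2 <- outer((seq_len(d[1]) - fx)^2, (seq_len(d[2]) - fy)^2, "+")
    fib <- fib2 <= p$fibula_radius^2
    for (z in seq_len(d[3])) vol[, , z][fib & vol[, , z] == ints["air"]] <- ints["cortical"]
    if (d[3] >= 2L) {
      z1 <- max(1L, d[3] %/% 2L)
      z2 <- z1 + 1L
      yr <- round(cy)
      x_t <- max(which(labels[, yr, z2] == 1L))       # tibia outer edge
      x_f <- min(which(fib[, yr]))                    # fibula inner edge
      gap <- x_f - x_t - 1L
      if (gap >= 2L) {
        # tibia-side spur (slice z2) is bone of the tibia; the remaining gap
        # voxels (slice z1) are fibula material reaching the fibula in-plane.
        # The spur and the first gap voxel are diagonally 26-adjacent across
        # the two slices, so the bones connect in 3D but never in-plane.
        labels[x_t + 1L, yr, z2] <- 1L
        vol[x_t + 1L, yr, z2] <- ints["cortical"]
        vol[(x_t + 2L):(x_f - 1L), yr, z1] <- ints["cortical"]
      }
    }
  }
  # holder/resin slab along the x edge
  if (p$holder_width > 0) {
    hw <- seq_len(min(p$holder_width, d[1]))
    sl <- vol[hw, , ]
    sl[sl == ints["air"]] <- ints["resin"]
    vol[hw, , ] <- sl
  }
  if (p$noise_sigma > 0) vol <- vol + stats::rnorm(prod(d), 0, p$noise_sigma)
  list(volume = intensity_volume(vol, p$spacing),
       labels = label_map(labels, p$spacing))
}

#' Degrade a phantom to emulate treatment effects
#'
#' Modes emulate altered bone morphology: `porosity` punches random holes in
#' the cortical shell, `thin` erodes the cortex by one voxel, `sparsify`
#' randomly deletes trabecular voxels, `densify` dilates trabeculae into the
#' cavity, `identity` returns the input. Labels and intensities are updated
#' consistently.
#'
#' @param vol an [intensity_volume()].
#' @param labels the paired [label_map()].
#' @param mode degradation mode.
#' @param amount mode strength: hole fraction for `porosity` (default 0.05),
#'   deletion probability for `sparsify` (default 0.5), fraction of the
#'   one-voxel dilation shell added for `densify` (default 0.3, a moderate
#'   anabolic gain); unused for `thin`.
#' @param seed RNG seed for the stochastic modes.
#' @return `list(volume, labels)`.
#' @export
degrade_phantom <- function(vol, labels, mode = c("identity", "porosity",
                                                  "thin", "sparsify", "densify"),
                            amount = NULL, seed = 1L) {
  mode <- match.arg(mode)
  check_geometry(vol, labels)
  if (mode == "identity") return(list(volume = vol, labels = labels))
  v <- vol$voxels
  l <- labels$voxels
  bg_int <- mean(v[l == 0L])
  with_seed(seed, {
    if (mode == "porosity") {
      f <- amount %||% 0.05
      idx <- which(l == 1L)
      hit <- idx[stats::runif(length(idx)) < f]
      l[hit] <- 0L
      v[hit] <- bg_int
    } else if (mode == "thin") {
      cort <- l == 1L
      keep <- binary_erode(cort, 1)
      gone <- cort & !keep
      l[gone] <- 0L
      v[gone] <- bg_int
    } else if (mode == "sparsify") {
      f <- amount %||% 0.5
      idx <- which(l == 2L)
      hit <- idx[stats::runif(length(idx)) < f]
      l[hit] <- 0L
      v[hit] <- bg_int
    } else if (mode == "densify") {
      f <- amount %||% 0.3
      grown <- which(binary_dilate(l == 2L, 1) & l == 0L)
      hit <- grown[stats::runif(length(grown)) < f]
      l[hit] <- 2L
      v[hit] <- mean(v[labels$voxels == 2L])
    }
  })
  list(volume = intensity_volume(v, vol$spacing, vol$units),
       labels = label_map(l, labels$spacing))
}
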