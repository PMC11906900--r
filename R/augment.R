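# Live training-time augmentation. Five transform families, each applied
# independently with a small probability per sample: random affine (z-axis
# rotation + isotropic scale), elastic deformation, additive Gaussian noise,
# intensity scaling, and gamma contrast. Geometric transforms apply one
# shared mapping to image (trilinear) and labels (nearest neighbour).

# trilinear resampling at continuous source coordinates (1-based);
# out-of-bounds samples take `fill`
resample_trilinear <- function(a, sx, sy, sz, fill) {
  d <- dim(a)
  eps <- 1e-6   # tolerate float round-off at the volume faces
  inb <- sx >= 1 - eps & sx <= d[1] + eps & sy >= 1 - eps & sy <= d[2] + eps &
         sz >= 1 - eps & sz <= d[3] + eps
  sx <- pmin(pmax(sx, 1), d[1]); sy <- pmin(pmax(sy, 1), d[2])
  sz <- pmin(pmax(sz, 1), d[3])
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  out <- numeric(length(sx))
  out[!inb] <- fill
  gx0 <- pmin(pmax(x0, 1L), d[1]); gx1 <- pmin(gx0 + 1L, d[1])
  gy0 <- pmin(pmax(y0, 1L), d[2]); gy1 <- pmin(gy0 + 1L, d[2])
  gz0 <- pmin(pmax(z0, 1L), d[3]); gz1 <- pmin(gz0 + 1L, d[3])
  at <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(gx0, gy0, gz0) +
       fx * (1 - fy) * (1 - fz) * at(gx1, gy0, gz0) +
       (1 - fx) * fy * (1 - fz) * at(gx0, gy1, gz0) +
       fx * fy * (1 - fz) * at(gx1, gy1, gz0) +
       (1 - fx) * (1 - fy) * fz * at(gx0, gy0, gz1) +
       fx * (1 - fy) * fz * at(gx1, gy0, gz1) +
       (1 - fx) * fy * fz * at(gx0, gy1, gz1) +
       fx * fy * fz * at(gx1, gy1, gz1)
  out[inb] <- v[inb]
  array(out, d)
}

resample_nearest <- function(a, sx, sy, sz, fill) {
  d <- dim(a)
  ix <- round(sx); iy <- round(sy); iz <- round(sz)
  inb <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2] & iz >= 1L & iz <= d[3]
  out <- rep(fill, length(sx))
  out[inb] <- a[cbind(ix[inb], iy[inb], iz[inb])]
  array(out, d)
}

resample_sample <- function(sample, sx, sy, sz) {
  img <- sample$image$voxels
  lab <- sample$labels$voxels
  img2 <- resample_trilinear(img, sx, sy, sz, fill = min(img))
  lab2 <- resample_nearest(lab, sx, sy, sz, fill = 0L)
  list(image = intensity_volume(img2, sample$image$spacing, sample$image$units),
       labels = label_map(lab2, sample$labels$spacing))
}

#' Random affine transform (rotation about z, isotropic scale)
#'
#' Rotation angle ~ U over `rot_range` about the z axis and isotropic scale
#' ~ U over `scale_range`, applied about the volume centre; the image is
#' resampled trilinearly, labels by nearest neighbour with the identical
#' transform. Shape is unchanged; uncovered voxels are filled with the image
#' minimum (labels: background).
#'
#' @param sample `list(image = intensity_volume, labels = label_map)`.
#' @param cfg an [augment_config()].
#' @param angle,scale optional fixed values overriding the random draw.
#' @return the transformed sample.
#' @export
random_affine <- function(sample, cfg = augment_config(), angle = NULL,
                          scale = NULL) {
  if (is.null(angle)) angle <- stats::runif(1, cfg$rot_range[1], cfg$rot_range[2])
  if (is.null(scale)) scale <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  if (angle == 0 && scale == 1) return(sample)
  d <- dim(sample$image$voxels)
  ctr <- (d + 1) / 2
  g <- grid_coords(d) + 1  # 1-based voxel coordinates
  px <- g[, 1] - ctr[1]; py <- g[, 2] - ctr[2]; pz <- g[, 3] - ctr[3]
  ca <- cos(-angle); sa <- sin(-angle)   # inverse rotation for pull sampling
  sx <- (ca * px - sa * py) / scale + ctr[1]
  sy <- (sa * px + ca * py) / scale + ctr[2]
  sz <- pz / scale + ctr[3]
  resample_sample(sample, sx, sy, sz)
}

#' Elastic deformation
#'
#' Displacement `x' = x + alpha * G(sigma)` per axis, where `G(sigma)` is a
#' standard-normal random field smoothed with a Gaussian kernel of sd
#' `sigma ~ U[9, 13]` voxels and `alpha ~ U[0, 900]` scales it. Smoothing a
#' unit-variance field at these widths shrinks its amplitude by two to three
#' orders of magnitude, so the resulting displacements are a few voxels.
#' Image and labels are warped by the same field.
#'
#' @param sample `list(image, labels)`.
#' @param cfg an [augment_config()].
#' @param alpha,sigma optional fixed values overriding the random draws.
#' @return the transformed sample.
#' @export
elastic_deform <- function(sample, cfg = augment_config(), alpha = NULL,
                           sigma = NULL) {
  if (is.null(sigma)) sigma <- stats::runif(1, cfg$elastic_sigma[1], cfg$elastic_sigma[2])
  if (is.null(alpha)) alpha <- stats::runif(1, cfg$elastic_alpha[1], cfg$elastic_alpha[2])
  if (alpha == 0) return(sample)
  d <- dim(sample$image$voxels)
  n <- prod(d)
  field <- lapply(1:3, function(i)
    alpha * as.vector(gaussian_smooth_3d(array(stats::rnorm(n), d), sigma)))
  g <- grid_coords(d) + 1
  resample_sample(sample, g[, 1] + field[[1]], g[, 2] + field[[2]],
                  g[, 3] + field[[3]])
}

#' Additive Gaussian noise
#'
#' `x' = x + N(0, noise_variance)`; labels untouched.
#'
#' @param sample `list(image, labels)`.
#' @param cfg an [augment_config()].
#' @return the transformed sample.
#' @export
add_gaussian_noise <- function(sample, cfg = augment_config()) {
  if (cfg$noise_variance == 0) return(sample)
  v <- sample$image$voxels
  v <- v + stats::rnorm(length(v), 0, sqrt(cfg$noise_variance))
  sample$image <- intensity_volume(array(v, dim(sample$image$voxels)),
                                   sample$image$spacing, sample$image$units)
  sample
}

#' Random intensity scaling
#'
#' `x' = x * (1 + f)` with `f ~ U` over `intensity_range`; labels untouched.
#'
#' @param sample `list(image, labels)`.
#' @param cfg an [augment_config()].
#' @param f optional fixed scaling factor.
#' @return the transformed sample.
#' @export
scale_intensity <- function(sample, cfg = augment_config(), f = NULL) {
  if (is.null(f)) f <- stats::runif(1, cfg$intensity_range[1], cfg$intensity_range[2])
  sample$image <- intensity_volume(sample$image$voxels * (1 + f),
                                   sample$image$spacing, sample$image$units)
  sample
}

#' Random gamma contrast adjustment
#'
#' `x' = x^gamma` with `gamma ~ U` over `gamma_range`, evaluated on a
#' min-max-[0, 1]-rescaled copy and mapped back to the original range (a
#' power law is undefined for the negative values of z-scored data).
#' Monotone in the input intensity; labels untouched.
#'
#' @param sample `list(image, labels)`.
#' @param cfg an [augment_config()].
#' @param gamma optional fixed exponent.
#' @return the transformed sample.
#' @export
adjust_contrast <- function(sample, cfg = augment_config(), gamma = NULL) {
  if (is.null(gamma)) gamma <- stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
  v <- sample$image$voxels
  rng <- range(v)
  if (rng[1] < rng[2]) {
    u <- (v - rng[1]) / (rng[2] - rng[1])
    v <- u^gamma * (rng[2] - rng[1]) + rng[1]
  }
  sample$image <- intensity_volume(v, sample$image$spacing, sample$image$units)
  sample
}

#' Apply the live augmentation stack
#'
#' Each of the five transforms fires independently with probability `p`, in
#' the fixed order affine, elastic, noise, intensity, contrast. Fully
#' reproducible given the RNG state (seed before calling).
#'
#' @param sample `list(image, labels)`.
#' @param cfg an [augment_config()].
#' @return the augmented sample.
#' @export
apply_augmentations <- function(sample, cfg = augment_config()) {
  if (stats::runif(1) < cfg$p) sample <- random_affine(sample, cfg)
  if (stats::runif(1) < cfg$p) sample <- elastic_deform(sample, cfg)
  if (stats::runif(1) < cfg$p) sample <- add_gaussian_noise(sample, cfg)
  if (stats::runif(1) < cfg$p) sample <- scale_intensity(sample, cfg)
  if (stats::runif(1) < cfg$p) sample <- adjust_contrast(sample, cfg)
  sample
}
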