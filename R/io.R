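# Volume and label containers, NIfTI round trip, z-subset splitting, and the
# configuration records for every pipeline stage.
#
# Axis convention throughout the package: arrays are indexed (x, y, z) with z
# the long bone axis; per-slice operations iterate over z. Spacing is carried
# in micrometres internally; metric reporting converts to millimetres.

#' Intensity volume
#'
#' A 3D scalar grid with physical voxel spacing.
#'
#' @param voxels 3D numeric array `(H, W, D)`, all values finite.
#' @param spacing voxel spacing `(sx, sy, sz)` in micrometres.
#' @param units intensity tag: `"raw-scanner"`, `"8-bit"` or `"z-scored"`.
#' @return an object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, spacing = c(1, 1, 1),
                             units = c("raw-scanner", "8-bit", "z-scored")) {
  units <- match.arg(units)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (micrometres)")
  if (!all(is.finite(voxels))) stop("all voxel values must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing), units = units),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("intensity volume %d x %d x %d, spacing (%.3g, %.3g, %.3g) um, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Label map
#'
#' Integer voxel labels sharing geometry with a paired intensity volume:
#' 0 = background, 1 = cortical bone, 2 = trabecular bone.
#'
#' @param voxels 3D integer array with values in `{0, 1, 2}`.
#' @param spacing voxel spacing in micrometres.
#' @return an object of class `label_map`.
#' @export
label_map <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(voxels %in% c(0L, 1L, 2L))) stop("labels must be in {0, 1, 2}")
  storage.mode(voxels) <- "integer"
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$voxels)
  n <- tabulate(x$voxels + 1L, 3L)
  cat(sprintf("label map %d x %d x %d: background %d, cortical %d, trabecular %d\n",
              d[1], d[2], d[3], n[1], n[2], n[3]))
  invisible(x)
}

check_geometry <- function(vol, labels) {
  if (!identical(dim(vol$voxels), dim(labels$voxels)))
    stop("volume and label geometry differ")
  invisible(TRUE)
}

#' Read a volume from NIfTI
#'
#' Reads a 3D single-channel NIfTI file (optionally gzipped). Trailing
#' singleton dimensions (e.g. a stored `(H, W, D, 1)` shape) are squeezed.
#' Header pixel dimensions are interpreted as micrometres; a missing or
#' degenerate spacing falls back to `(1, 1, 1)` um with a warning.
#'
#' @param path file path.
#' @param labels read as a [label_map()] instead of an [intensity_volume()].
#' @return an [intensity_volume()] or [label_map()].
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) > 3L) {
    if (any(d[-(1:3)] != 1L)) stop("volume has more than 3 non-singleton dimensions")
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected a 3D volume")
  a <- array(as.vector(a), d)   # drop NIfTI header attributes
  sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) rep(NA_real_, 3))
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    warning("header lacks a usable voxel spacing; defaulting to (1, 1, 1) um")
    sp <- c(1, 1, 1)
  }
  if (labels) label_map(a, spacing = sp)
  else intensity_volume(a, spacing = sp)
}

#' Write a volume to NIfTI
#'
#' Intensity volumes are stored as 64-bit floats, label maps as unsigned
#' 8-bit integers; voxel spacing is written to the header pixel dimensions
#' (micrometres).
#'
#' @param x an [intensity_volume()] or [label_map()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path) {
  is_lab <- inherits(x, "label_map")
  if (!is_lab && !inherits(x, "intensity_volume"))
    stop("x must be an intensity_volume or label_map")
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = if (is_lab) "uint8" else "double")
  invisible(path)
}

#' Split a scan into z-subsets
#'
#' Divides a volume (and its labels) into `n` contiguous, non-overlapping
#' slabs along the z (long bone) axis, covering every slice. Slab depths
#' differ by at most one; the remainder goes to the leading (proximal)
#' slabs.
#'
#' @param volume an [intensity_volume()].
#' @param labels an optional [label_map()] with matching geometry.
#' @param n number of subsets (evaluation protocol: 10 per scan).
#' @return a list of `n` elements, each `list(volume, labels, z_range)`.
#' @export
split_z_subsets <- function(volume, labels = NULL, n = 10L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  D <- dim(volume$voxels)[3L]
  if (n > D) stop(sprintf("cannot split %d slices into %d subsets", D, n))
  if (!is.null(labels)) check_geometry(volume, labels)
  base <- D %/% n
  depths <- rep(base, n)
  r <- D %% n
  if (r > 0L) depths[seq_len(r)] <- base + 1L
  ends <- cumsum(depths)
  starts <- ends - depths + 1L
  lapply(seq_len(n), function(i) {
    zr <- starts[i]:ends[i]
    out <- list(volume = intensity_volume(volume$voxels[, , zr, drop = FALSE],
                                          volume$spacing, volume$units),
                z_range = c(starts[i], ends[i]))
    if (!is.null(labels))
      out$labels <- label_map(labels$voxels[, , zr, drop = FALSE], labels$spacing)
    out
  })
}

## ---- configuration records ----

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: SGD with momentum 0.99, batch
#' size 4, cosine annealing from 1e-4, random crops of (320, 320, 32), a
#' 70/10/20 scan-level split, equal Dice and cross-entropy weights, and 10
#' z-subsets per scan for evaluation.
#'
#' @param lr0 initial learning rate.
#' @param momentum SGD momentum.
#' @param batch_size crops per optimisation step.
#' @param crop training subvolume extents.
#' @param split `(train, val, test)` fractions, summing to one.
#' @param max_steps optimisation step budget.
#' @param steps_per_epoch validation cadence.
#' @param seed RNG seed for cropping/augmentation/batching.
#' @param loss_alpha,loss_beta Dice and cross-entropy weights (sum to one).
#' @param n_subsets z-subsets per scan in evaluation.
#' @param E patch-embedding reduction (used to validate crop divisibility).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, momentum = 0.99, batch_size = 4L,
                         crop = c(320L, 320L, 32L), split = c(0.7, 0.1, 0.2),
                         max_steps = 200L, steps_per_epoch = 250L, seed = 1L,
                         loss_alpha = 0.5, loss_beta = 0.5, n_subsets = 10L,
                         E = c(4L, 4L, 2L)) {
  if (abs(sum(split) - 1) > 1e-8) stop(sprintf(
    "split fractions must sum to 1 (got %.4g)", sum(split)))
  if (abs(loss_alpha + loss_beta - 1) > 1e-8)
    stop("loss_alpha + loss_beta must equal 1")
  if (lr0 < 0 || momentum < 0 || momentum >= 1) stop("invalid optimiser settings")
  crop <- as.integer(crop)
  need <- as.integer(E) * 8L
  if (any(crop %% need != 0L))
    stop(sprintf("crop extents (%s) must be divisible by E*8 = (%s)",
                 paste(crop, collapse = ","), paste(need, collapse = ",")))
  structure(list(lr0 = lr0, momentum = momentum, batch_size = as.integer(batch_size),
                 crop = crop, split = split, max_steps = as.integer(max_steps),
                 steps_per_epoch = as.integer(steps_per_epoch), seed = as.integer(seed),
                 loss_alpha = loss_alpha, loss_beta = loss_beta,
                 n_subsets = as.integer(n_subsets)),
            class = "train_config")
}

#' Preprocessing configuration
#'
#' @param margin integer margin `M` subtracted from the Otsu threshold
#'   (8-bit gray levels; default 5).
#' @param histogram_bins histogram resolution for thresholding.
#' @param crop_margin voxels retained around the bone bounding box.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(margin = 5L, histogram_bins = 256L, crop_margin = 2L) {
  if (margin < 0L) stop("margin must be >= 0")
  if (histogram_bins < 2L) stop("histogram_bins must be >= 2")
  if (crop_margin < 0L) stop("crop_margin must be >= 0")
  structure(list(margin = as.integer(margin),
                 histogram_bins = as.integer(histogram_bins),
                 crop_margin = as.integer(crop_margin)),
            class = "preprocess_config")
}

#' Postprocessing configuration
#'
#' @param opening_radius spherical opening radius `K_o` (voxels) for
#'   endosteal smoothing (default 3).
#' @param closing_radius spherical closing radius `R_c` (voxels) for
#'   trabecular reconnection (default 1).
#' @param smooth,connect stage switches.
#' @return an object of class `postprocess_config`.
#' @export
postprocess_config <- function(opening_radius = 3L, closing_radius = 1L,
                               smooth = TRUE, connect = TRUE) {
  if (opening_radius < 1L || closing_radius < 1L)
    stop("structuring element radii must be >= 1")
  structure(list(opening_radius = as.integer(opening_radius),
                 closing_radius = as.integer(closing_radius),
                 smooth = isTRUE(smooth), connect = isTRUE(connect)),
            class = "postprocess_config")
}

#' Live augmentation configuration
#'
#' Parameter ranges of the five training-time transform families: rotation
#' about z in `[0, pi]` with isotropic scaling in `[0.85, 1.25]`; elastic
#' deformation with smoothing sd in `[9, 13]` voxels and magnitude in
#' `[0, 900]`; additive Gaussian noise of variance 0.1; intensity scaling by
#' `1 + f`, `f` in `[-0.1, 0.1]`; and gamma contrast in `[0.5, 4.5]`. Each
#' transform fires independently with probability `p = 0.1`.
#'
#' @param p per-transform application probability.
#' @param rot_range rotation angle range (radians, about z).
#' @param scale_range isotropic scale factor range.
#' @param elastic_sigma smoothing sd range (voxels).
#' @param elastic_alpha displacement magnitude range.
#' @param noise_variance additive Gaussian noise variance.
#' @param intensity_range intensity scaling factor range.
#' @param gamma_range contrast exponent range.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(p = 0.1, rot_range = c(0, pi),
                           scale_range = c(0.85, 1.25),
                           elastic_sigma = c(9, 13), elastic_alpha = c(0, 900),
                           noise_variance = 0.1, intensity_range = c(-0.1, 0.1),
                           gamma_range = c(0.5, 4.5)) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  rng <- list(rot_range = rot_range, scale_range = scale_range,
              elastic_sigma = elastic_sigma, elastic_alpha = elastic_alpha,
              intensity_range = intensity_range, gamma_range = gamma_range)
  for (nm in names(rng)) {
    v <- rng[[nm]]
    if (length(v) != 2L || v[1] > v[2]) stop(sprintf("%s must be an ordered pair", nm))
  }
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  structure(c(list(p = p, noise_variance = noise_variance), rng),
            class = "augment_config")
}

#' Load all pipeline configurations from a YAML file
#'
#' A flat key/value YAML document; every key is optional and missing keys
#' take the reference protocol defaults (`C = 96`, `E = [4, 4, 2]`,
#' `heads = [6, 12, 24, 48]`, `lr0 = 1e-4`, `momentum = 0.99`,
#' `batch_size = 4`, `crop = [320, 320, 32]`, `loss_alpha = loss_beta = 0.5`,
#' `margin = 5`, `opening_radius = 3`, `closing_radius = 1`, `p = 0.1`).
#' Invariant violations are reported with the offending key.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a list with elements `model`, `train`, `preprocess`,
#'   `postprocess`, `augment`.
#' @export
load_config <- function(path = NULL) {
  kv <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  pick <- function(fn, keys, rename = NULL) {
    args <- kv[intersect(names(kv), keys)]
    if (!is.null(rename))
      names(args) <- ifelse(names(args) %in% names(rename),
                            unlist(rename[names(args)]), names(args))
    tryCatch(do.call(fn, args), error = function(e)
      stop(sprintf("invalid configuration (%s): %s",
                   paste(names(args), collapse = ","), conditionMessage(e)),
           call. = FALSE))
  }
  model <- pick(dbahnet_config,
                c("C", "E", "heads", "depths", "window", "mlp_ratio", "n_classes"))
  # crop divisibility must hold against the configured E
  tr_args <- kv[intersect(names(kv), c("lr0", "momentum", "batch_size", "crop",
                                       "split", "max_steps", "steps_per_epoch",
                                       "seed", "loss_alpha", "loss_beta",
                                       "n_subsets"))]
  tr_args$E <- model$E
  train <- tryCatch(do.call(train_config, tr_args), error = function(e)
    stop(sprintf("invalid configuration (crop): %s", conditionMessage(e)),
         call. = FALSE))
  list(model = model,
       train = train,
       preprocess = pick(preprocess_config,
                         c("margin", "histogram_bins", "crop_margin")),
       postprocess = pick(postprocess_config,
                          c("opening_radius", "closing_radius", "smooth", "connect")),
       augment = pick(augment_config,
                      c("p", "rot_range", "scale_range", "elastic_sigma",
                        "elastic_alpha", "noise_variance", "intensity_range",
                        "gamma_range")))
}
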