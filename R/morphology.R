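# Binary 3D morphology and component analysis, built on the compiled exact
# Euclidean distance transform: dilation by a discrete Euclidean ball of
# radius r is the set of voxels within distance r of the foreground, and
# erosion is its dual. This gives exact ball structuring elements (the
# discretisation is "all integer offsets with |o| <= r") and O(N) cost.

#' Label connected components
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (faces) or 26 (faces, edges, vertices). For a
#'   single-slice array, 26 reduces to the usual 2D 8-connectivity.
#' @return integer array of component labels (0 = background) with attribute
#'   `n_components`; labels are assigned in raster-scan order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6L, 26L))
  lab <- .cc_label_3d(as.logical(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim(mask))
  attr(lab, "n_components") <- n
  lab
}

#' Euclidean distance transform
#'
#' Distance (in spacing units) from every voxel to the nearest foreground
#' voxel centre; `Inf` when the mask is empty.
#'
#' @param mask 3D logical array.
#' @param spacing per-axis voxel spacing.
#' @param squared return squared distances.
#' @return numeric array of distances.
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1), squared = FALSE) {
  stopifnot(length(dim(mask)) == 3L)
  if (!any(mask)) return(array(Inf, dim(mask)))
  d2 <- array(.edt_3d(as.logical(mask), dim(mask), as.numeric(spacing)), dim(mask))
  d2[d2 >= 1e29] <- Inf   # sentinel used internally for unreachable voxels
  if (squared) d2 else sqrt(d2)
}

#' Binary morphology with a spherical structuring element
#'
#' The structuring element is the discrete Euclidean ball of the given
#' radius (all integer offsets with norm at most `r`). Border convention:
#' dilation treats out-of-volume voxels as background, erosion treats them
#' as foreground — a structure cut by the field of view (a bone shaft
#' continuing beyond the scanned region) is not artificially eroded at the
#' faces. The two operators still form an adjunction, so opening and
#' closing remain idempotent.
#'
#' @param mask 3D logical array.
#' @param r ball radius in voxels.
#' @return 3D logical array.
#' @export
binary_dilate <- function(mask, r) {
  if (!any(mask)) return(mask)
  distance_transform(mask, squared = TRUE) <= r^2 + 1e-9
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, r) {
  if (!any(mask)) return(mask)
  if (all(mask)) return(mask)
  distance_transform(!mask, squared = TRUE) > r^2 + 1e-9
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, r) binary_dilate(binary_erode(mask, r), r)

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, r) binary_erode(binary_dilate(mask, r), r)

# largest component of a logical mask; ties broken by the component whose
# minimum linear voxel index is smallest (i.e. the first one encountered in
# raster order, which is component label 1, 2, ... by construction)
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n_components")
  if (n == 0L) stop("mask has no foreground voxels")
  sizes <- tabulate(lab[lab > 0L], n)
  best <- which(sizes == max(sizes))[1L]
  lab == best
}
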