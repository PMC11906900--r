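# Postprocessing of predicted label maps: remove disconnected segmentation
# noise, smooth the endosteal cortical surface (reassigning opened-away
# voxels to trabecular bone), and reconnect trabecular fragments by a
# background-only morphological closing.

#' Remove disconnected segmentation noise
#'
#' Reduces the union of the foreground classes to its largest 26-connected
#' component; class identities inside it are preserved.
#'
#' @param labels a [label_map()] with non-empty foreground.
#' @return a [label_map()].
#' @export
remove_noise_components <- function(labels) {
  l <- labels$voxels
  fg <- l > 0L
  if (!any(fg)) stop("label map has no foreground voxels")
  keep <- largest_component(fg, 26L)
  l[!keep] <- 0L
  label_map(l, labels$spacing)
}

#' Smooth the endosteal cortical transition
#'
#' Applies a morphological opening (spherical structuring element, radius
#' `opening_radius`, default 3) to the cortical mask and relabels every
#' voxel the opening removes as trabecular bone: small spurs and openings at
#' the endosteum become trabecular instead of vanishing, so the total
#' cortical + trabecular voxel count is conserved exactly.
#'
#' @param labels a [label_map()].
#' @param cfg a [postprocess_config()].
#' @return a [label_map()].
#' @export
smooth_endosteal_transition <- function(labels, cfg = postprocess_config()) {
  l <- labels$voxels
  cort <- l == 1L
  if (!any(cort)) return(labels)
  opened <- binary_open(cort, cfg$opening_radius)
  moved <- cort & !opened
  l[moved] <- 2L
  label_map(l, labels$spacing)
}

#' Reconnect trabecular fragments
#'
#' Morphological closing (spherical structuring element, radius
#' `closing_radius`, default 1) on the trabecular mask merges components
#' separated by small gaps. Bridge voxels are taken only from background —
#' cortical voxels are never relabelled — and trabecular voxels are never
#' removed, so the trabecular component count is non-increasing.
#'
#' @param labels a [label_map()].
#' @param cfg a [postprocess_config()].
#' @return a [label_map()].
#' @export
connect_trabeculae <- function(labels, cfg = postprocess_config()) {
  l <- labels$voxels
  trab <- l == 2L
  if (!any(trab)) return(labels)
  # closing restricted to background: the dilation never grows into the
  # cortical compartment, so no bridge is supported by cortical voxels
  dil <- binary_dilate(trab, cfg$closing_radius) & l != 1L
  closed <- binary_erode(dil, cfg$closing_radius)
  bridge <- closed & l == 0L
  l[bridge] <- 2L
  label_map(l, labels$spacing)
}

#' Full postprocessing pipeline
#'
#' Noise removal, endosteal smoothing, trabecular reconnection, in that
#' order; each stage can be switched off in the configuration. Per-class
#' voxel deltas are attached as attribute `deltas`.
#'
#' @param labels a [label_map()].
#' @param cfg a [postprocess_config()].
#' @param verbose print per-class voxel deltas.
#' @return a [label_map()] with attribute `deltas`.
#' @export
postprocess_pipeline <- function(labels, cfg = postprocess_config(),
                                 verbose = FALSE) {
  counts <- function(l) tabulate(l$voxels + 1L, 3L)
  before <- counts(labels)
  out <- remove_noise_components(labels)
  if (cfg$smooth) out <- smooth_endosteal_transition(out, cfg)
  if (cfg$connect) out <- connect_trabeculae(out, cfg)
  after <- counts(out)
  deltas <- after - before
  names(deltas) <- c("background", "cortical", "trabecular")
  if (verbose)
    message(sprintf("postprocess deltas: background %+d, cortical %+d, trabecular %+d",
                    deltas[1], deltas[2], deltas[3]))
  attr(out, "deltas") <- deltas
  out
}
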