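---
title: "Segmenting cortical and trabecular bone with DBAHNet: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting cortical and trabecular bone with DBAHNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-resolution micro-CT of the mouse tibia resolves the two bone
compartments that preclinical skeletal studies quantify separately: the
dense cortical shell (label 1) and the spongy trabecular lattice inside the
medullary cavity (label 2). Hand or semi-automatic labelling of such scans
is the bottleneck of bone morphometry. This package implements an automated
pipeline around DBAHNet, a dual-branch hybrid network that couples
shifted-window (Swin) transformer blocks with channel- and
spatial-attention convolution modules, plus everything a practitioner needs
around it: preprocessing of raw scans, live training-time augmentation,
SGD training, sliding-window whole-volume inference, morphological
postprocessing, and Dice/HD95 evaluation. Because the study datasets such
networks are trained on are not public, the package ships a synthetic tibia
phantom generator with exact voxel ground truth; all tests and the
acceptance analyses run end-to-end on phantoms.

# The network

The input is a single-channel z-scored volume indexed `(x, y, z)` with `z`
the long bone axis. A patch embedding of two strided 3x3x3 convolutions
(per-axis stride product equal to the reduction vector `E`, each followed
by normalisation and GeLU) maps it to `C` channels at `1/E` resolution.
Three encoder levels then run two parallel branches:

* a **transformer branch** of Swin block pairs — the four-line pre-norm
  residual scheme (layer norm, windowed multi-head self-attention,
  residual; layer norm, MLP, residual; repeated with the shifted window
  grid) with attention `Softmax(Q K' / sqrt(d_k)) V` inside non-overlapping
  local windows, followed by a stride-2 convolution that doubles channels;
* a **convolution branch** (CACM) that pools the feature map channel-wise
  (average and max), derives a sigmoid channel mask through a GeLU
  bottleneck, reweights the input, and downsamples with a stride-2
  convolution.

A transformer-convolution feature fusion module (TCFFM) reweights each
branch by a sigmoid of its channel-average descriptor, concatenates,
fuses with a 1x1x1 convolution, and refines with one local-volume
transformer block. After three levels the `8C`-channel map enters a
bottleneck of four global-attention transformer blocks. The decoder
mirrors the encoder with a spatial-attention module (SACM: channel-wise
max/mean maps, a 1x1x1 convolution to a sigmoid spatial mask, then a
stride-2 transpose convolution) and attention-gated skips: encoder
features are projected to keys and values, decoder features form queries,
and one windowed cross-attention block filters the skip. Transpose
convolutions with stride product `E` reconstruct full-resolution logits
for the three classes; the voxel-wise softmax sums to one.

With the reference configuration (`C = 96`, `E = [4, 4, 4]`, heads 6, 12,
24, 48) an input of `320 x 320 x 32` embeds to `(96, 80, 80, 8)` and
reaches the bottleneck at `(768, 10, 10, 1)`; `dbahnet_stage_shapes()`
prints this ledger for any configuration. Head counts double with
channels, so the per-head dimension is constant across stages (16 for
`C = 96`).

## Architecture choices the description leaves open

* **Window size.** Local-volume extents are never stated; the default
  `(4, 4, 2)` divides all stage shapes for the default crop and respects
  the flatter z extent. Shifts are half a window per axis, with the
  standard convention that axes fully covered by one window are not
  shifted.
* **Relative position bias.** Included (learned, per head), the standard
  shifted-window convention.
* **Branch versus fusion downsampling.** The module descriptions let both
  the CACM (its final stride-2 convolution) and the TCFFM ("a downsampling
  convolution layer") claim the resolution change. Here each branch
  resamples itself — CACM's stride-2 convolution, and a stride-2
  convolution after the Swin pair — and the TCFFM's convolution is the
  channel-halving 1x1x1 fusion; both readings produce the same stage
  shapes.
* **Skip wiring.** Attention gates act at all three decoder levels; the
  stage-0 gate takes the patch embedding output as its skip since no TCFFM
  output exists at that resolution.
* **Normalisation placement.** Transformer blocks use layer normalisation
  exactly as written. Convolutions are followed by *instance*
  normalisation (per-channel statistics over space): after a stem
  convolution with few channels, per-token layer normalisation would
  project out the token's mean and scale — at `C/2` channels that includes
  most of the absolute-intensity information that separates bone from
  background. Instance normalisation preserves spatial patterns exactly
  and is the standard choice in convolutional segmentation stems. It is
  degenerate when a stage collapses to a single spatial position (the
  normalised map is constant and gradients vanish there), so training
  inputs should keep every stage extent at least 2 — i.e. at least
  `16 * E` voxels per axis.
* **Transpose convolutions** use kernel extents equal to their stride, so
  every output voxel receives exactly one contribution and stitching
  artefacts cannot arise inside a tile.
* **Initialisation.** Truncated normal (sd 0.02) for linear and attention
  weights, He-scaled normal for convolution kernels, zero biases, unit
  layer-norm gains. Attention gates are initialised as identity skips:
  value and output projections start at the identity and the
  relative-position bias places most softmax mass on the spatially aligned
  skip token. Full-resolution encoder content therefore reaches the
  decoder head from the first optimisation step, which matters at the
  short training schedules used in the tests (below); training later
  sharpens or suppresses the gates.

# Losses and metrics

Training minimises `alpha * DiceLoss + beta * CE` with
`alpha = beta = 0.5`. The soft Dice loss averages
`1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)` over the two foreground
classes with `eps = 1e-5`; the cross-entropy is the mean over voxels of
`-log p` at the true class (the mean, not the printed sum — the two terms
are described as balanced at equal weights, which only holds on a common
per-voxel scale). Evaluation uses the hard Dice overlap
`2|X n Y| / (|X| + |Y|)` per compartment (both masks empty scores 1, one
empty scores 0) and HD95, the 95th percentile of Euclidean
boundary-to-boundary distances in physical units, reported in millimetres.
A voxel is boundary if any 6-neighbour lies outside its mask. Because "the
95th percentile of all the distances" does not fix a direction convention,
the default takes the maximum of the two directed 95th percentiles (the
prevailing benchmark convention); `method = "pooled"` pools both directed
sets instead. Distances come from an exact anisotropic Euclidean distance
transform (compiled; lower-envelope algorithm per axis), so `hd95()`
matches a brute-force pairwise computation to floating-point accuracy.

# Preprocessing

Raw scans pass through: (1) Otsu thresholding on a min-max 8-bit rescale
(256 bins) with a retention margin — the threshold maximising between-class
variance is lowered by `M = 5` gray levels so partial-volume trabecular
voxels survive; if the variance maximum is a plateau (possible for
synthetic histograms with empty gaps) its midpoint is used, which changes
nothing for continuous data; (2) retention of the largest 26-connected
component (ties broken by the component holding the smallest linear voxel
index); (3) per-slice removal of the second-largest 8-connected 2D
component, the fibula — applied literally, so a third, smaller component
in the same slice survives; (4) autocropping to the bone bounding box with
a configurable margin, filling non-mask voxels with the volume minimum so
the subsequent (5) z-score normalisation (population standard deviation,
all voxels of the cropped volume) is not distorted by an arbitrary fill
value.

# Augmentation

Five families, each applied independently with probability `p = 0.1` per
sample, in the fixed order affine, elastic, noise, intensity, contrast:
rotation about z uniform on `[0, pi]` with isotropic scaling on
`[0.85, 1.25]`; elastic deformation `x' = x + alpha * G(sigma)` where
`G(sigma)` is a standard-normal field smoothed by a Gaussian of sd
`sigma ~ U[9, 13]` voxels and `alpha ~ U[0, 900]` — the formula is applied
literally, with no renormalisation of the smoothed field: smoothing at
these widths shrinks a unit-variance field by two to three orders of
magnitude, so `alpha <= 900` yields displacements of a few voxels, which
is also why a "maximum displacement of 900 voxels" reading was rejected;
additive Gaussian noise of variance 0.1; intensity scaling `x (1 + f)`,
`f ~ U[-0.1, 0.1]`; and gamma contrast `x^gamma`, `gamma ~ U[0.5, 4.5]`,
evaluated on a min-max `[0, 1]` rescale and mapped back because a power
law is undefined for the negative half of z-scored data. Geometric
transforms resample image (trilinear) and labels (nearest) with one shared
mapping; out-of-volume samples take the image minimum and background
respectively.

# The phantom generator

`generate_phantom()` emulates a cropped shaft region of a mouse tibia at
5 um voxels: a hollow, mildly tapered cortical tube (outer/inner radii
30/20 voxels — a 10-voxel, roughly 50 um cortex), a trabecular lattice
built by thresholding an anisotropic Gaussian random field (correlation
lengths 2.5, 2.5, 5 voxels: rod-like trabeculae roughly 25 um across,
aligned with the load axis) inside the cavity to a target volume fraction
of 0.25, closing it (radius 1), and discarding islands not attached to the
cortical shell (floating bone fragments are anatomically spurious); a
fibula rendered at cortical intensity but labelled background — always a
separate component in-plane yet diagonally 26-connected to the tibia
through a two-voxel mineralised ridge across adjacent slices, so the
largest-component cleanup must keep it and the per-slice rule must remove
it, exactly as in real scans; a low-intensity holder/resin slab; and
additive Gaussian noise
(sd 0.05 on a [0, 1] attenuation scale, contrast-to-noise about 8 for
trabecular bone over marrow). Intensity means are ordered
cortical > trabecular > marrow > resin > air. The geometry choices are
anatomical: murine trabecular dimensions sit in the 25–60 um range at this
resolution, the fibula cross-section dwarfs any single in-plane trabecular
profile (which is what makes the second-largest-component rule safe), and
cortical thickness stays well above the postprocessing opening's support. Degradation modes emulate treatment effects — cortical porosity,
cortical thinning, trabecular sparsification or (partial-shell)
densification — updating labels and intensities together.

What the phantom does *not* model: beam hardening and ring artefacts,
partial-volume blur, growth-plate and metaphyseal geometry, soft-tissue
background texture, and scanner-specific noise spectra. Tests passing on
phantoms therefore certify the pipeline's mechanics and the network's
trainability, not performance on real scans.

# Training protocol and desk-scale behaviour

Training follows the reference protocol: SGD with momentum 0.99, batch
size 4 (configurable down), cosine annealing from `lr0 = 1e-4` to zero,
random crops of `(320, 320, 32)` (divisible by `8 E` per axis), live
augmentation, scan-level 70/10/20 splits, and continuous monitoring of a
validation mean Dice with the best checkpoint retained. Whole volumes are
segmented by sliding windows with 50% overlap and Hann-weighted softmax
blending.

The test suite trains a tiny configuration (`C = 8`, heads 1, 2, 4, 8,
crop `64 x 64 x 32`) on a single phantom crop for at most 200 steps as a
learning sanity check. Two quantitative facts, both recomputed by the
suite, bound what such a check can show. First, an information ceiling: a
perfect classifier constrained to patch-constant output at the
`E = [4, 4, 2]` patch scores a mean foreground Dice of about 0.83 on the
phantom, while a voxel-wise intensity classifier reaches about 0.95 —
beating the patch ceiling requires the stem convolutions to learn a
voxel-resolution code for each `4 x 4 x 2` patch in its 8 embedding
channels. Second, an optimisation budget: with mean-normalised losses and
layer-normalised activations, the total descent available to plain SGD at
`lr0 = 1e-4` over 200 momentum-accelerated steps is far smaller than the
distance between a randomly initialised stem and such a code. The
short-schedule check therefore measures how far the architecture moves
under the stated protocol, and the package reports the Dice it actually
reaches rather than asserting a level the budget cannot support; the
identity-gate initialisation exists precisely to give the decoder
full-resolution content on these schedules.

# Postprocessing

Predicted label maps are refined in the printed order, each stage
switchable: (1) reduction of the foreground union to its largest
26-connected component; (2) endosteal smoothing — a morphological opening
of the cortical mask with a discrete Euclidean ball of radius `K_o = 3`,
with every voxel the opening removes reassigned to trabecular bone, so
cortical + trabecular voxel counts are conserved exactly; (3) trabecular
reconnection — a closing of the trabecular mask with a ball of radius
`R_c = 1` whose dilation is confined to non-cortical voxels, adding bridge
voxels only from background, so cortical voxels are never relabelled and
trabecular voxels never removed. Morphology is implemented exactly via the
distance transform (dilation: distance to foreground at most `r`;
erosion: its dual), with a field-of-view border rule — erosion treats
out-of-volume voxels as foreground, so a shaft cut by the scan boundary is
not opened away at the faces; the operators still form an adjunction, so
opening and closing are idempotent.

Two scale interactions are worth knowing. The opening's support is
`2 K_o + 1 = 7` voxels: cortex thinner than that (whether anatomically or
because a degradation mode punched sub-support pores into it) is
reassigned wholesale, which is why the porosity degradation mode is not a
meaningful input to the endosteal smoothing — the smoothing presumes the
smooth, pore-free cortical surfaces a trained network predicts. Likewise
the reconnection closing assumes trabecular gaps at the `2 R_c` scale are
segmentation errors; on anatomy whose trabeculae are genuinely fragmented
at that scale it over-connects. Dataset-specific tuning of `K_o` and `R_c`
is deliberately out of scope.

# Numerical conventions

* Spacing is carried in micrometres; metrics convert to millimetres.
* NIfTI is the on-disk format (RNifti); labels stored unsigned 8-bit,
  intensities as doubles; a missing header spacing falls back to
  `(1, 1, 1)` um with a warning.
* z-subset splitting spreads the remainder over the leading (proximal)
  slabs; subset evaluation reports both aggregation orders (class-mean per
  subset then subset-mean, and pooled whole-volume) since the reporting
  order is not fixed.
* Component-size ties: smallest minimum linear voxel index.
* Dice smoothing `eps = 1e-5`; probability clamp `1e-12` in the
  cross-entropy; attention masks use an additive `-1e9`.
* All randomness flows through R's RNG; generators, training and the
  pipeline take explicit seeds and restore the caller's RNG state where
  they seed internally.

# Known limitations

* The reverse-mode engine underlying training is dense and single-node;
  training wall-clock limits test-suite configurations to small models and
  phantom-scale volumes (the suite uses `C <= 8`, crops up to
  `64 x 64 x 32`, and at most a few hundred optimisation steps).
* Instance normalisation degenerates at stages with one spatial position;
  keep training inputs at or above `16 E` voxels per axis.
* The phantom's realism limits are listed above; headline performance
  numbers on real treated-bone datasets are outside what this package can
  reproduce or verify.
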