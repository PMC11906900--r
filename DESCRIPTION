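Package: dbahnet
Title: Dual-Branch Hybrid Transformer-CNN Segmentation of Cortical and
    Trabecular Bone in Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments cortical and trabecular bone compartments in 3D
    high-resolution micro-CT scans of mouse tibiae with DBAHNet, a
    dual-branch encoder-decoder that pairs shifted-window (Swin)
    transformer blocks with channel- and spatial-attention convolution
    modules, fused at every hierarchy level and trained with a combined
    Dice and cross-entropy loss. Ships the full surrounding pipeline:
    Otsu-with-margin preprocessing, live training-time augmentation,
    SGD training with cosine annealing, sliding-window inference,
    morphological postprocessing of the predicted label maps, and
    Dice/HD95 evaluation, together with a synthetic tibia phantom
    generator providing exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
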