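Package: xaiseg
Title: Weakly Supervised Tumour Segmentation from Classifier Attribution Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Repurposes a trained two-class image classifier as a weak
    segmenter for medical image slices. Computes gradient- and
    perturbation-based attribution heatmaps (saliency, input-times-gradient,
    guided backpropagation, Grad-CAM, guided Grad-CAM, occlusion, feature
    ablation, layer and neuron attributions) for the tumour class, converts
    them to binary segmentation masks with a thresholding / connected
    component / convex hull postprocessing pipeline, and evaluates the masks
    against ground truth with Dice and IoU. Includes a deterministic CNN
    engine with guided-backward support, a synthetic tumour-phantom
    generator so the whole pipeline is testable without clinical data, NIfTI
    axial slicing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    png,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
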