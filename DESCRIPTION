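Package: uroscope
Title: Virtual Ureteroscopy from Preoperative CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a delayed-phase CT volume of the kidney into
    simulated ureteroscopy views. Implements collecting-system extraction from
    a kidney segmentation (box dilation followed by three-class Otsu
    thresholding), iso-surface meshing of the binary result after Gaussian
    smoothing, wave-propagation curve-skeleton extraction from the triangle
    mesh, camera trajectory generation along the skeleton, an endoscopy-style
    ray-cast Phong renderer with configurable lighting presets, and
    distribution-distance evaluation of rendered image sets (Frechet and
    kernel inception distances) together with a patchwise contrastive loss and
    a desk-scale style-transfer smoke harness. A synthetic phantom generator
    (branching-tube collecting system inside a parenchyma shell, with
    ground-truth labels and centerline) makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
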