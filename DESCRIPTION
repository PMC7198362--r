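Package: bstemseg
Title: Brainstem Internal-Structure Segmentation from MP2RAGE Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of internal brainstem structures from MP2RAGE-derived
    images. Implements histogram-mode-anchored linear rescaling of the
    T1-weighted (UNI) image and the quantitative T1 map, construction of a
    contrast-enhanced RATIO image, six-class k-means voxel clustering on
    z-scored channel intensities, iterative diffeomorphic construction of
    probabilistic group priors, rule-based probabilistic refinement of the
    first-pass labels, segmentation quality indices (low-silhouette and
    miss-classification), ROI intensity extraction with group statistics, and
    Jacobian-based deformation morphometry with permutation family-wise error
    control. Ships a synthetic brainstem phantom generator with known
    ground-truth labels so the full pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
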