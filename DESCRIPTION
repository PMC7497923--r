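Package: CycleMIND
Title: Unsupervised Cycle-Consistent Deformable Registration of
    Multimodal 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end unsupervised deformable registration of multimodal
    3D medical volumes (e.g. pelvic CT/MR). Two fully convolutional
    networks regress dense displacement fields from a (moving, fixed)
    volume pair and are trained jointly with a modality-independent
    neighborhood descriptor (MIND) content loss, an L2 displacement
    regularizer and a cycle-reconstruction loss, so that no ground-truth
    deformations, segmentations or aligned training pairs are required.
    Includes NIfTI/MetaImage volume I/O with resampling, cropping and
    robust intensity normalization, differentiable trilinear warping,
    registration quality metrics (Dice coefficient, average surface
    distance, target registration error, Jacobian folding fraction) and a
    synthetic multimodal phantom generator with known ground-truth
    deformations for testing the whole pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
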