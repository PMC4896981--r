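Package: serialrecon
Title: Three-Dimensional Reconstruction of Images of Serial Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflows for reconstructing volumetric images from ordered
    stacks of 2D serial-section images: graph-based sequential affine
    alignment that skips heavily distorted sections via least-cost
    transform chains, iterative pairwise alignment of a stack to a 3D
    reference volume acting as a shape prior, coarse-to-fine merging of
    rigid transform series that removes z-shift while preserving
    section-to-section coherence, and iterative deformable refinement
    driven by neighborhood-average targets.  Includes an in-house
    intensity-based registration engine (rigid/affine 2D, affine 3D and
    Gaussian-regularized demons-style deformable 2D), NIfTI input and
    output, synthetic phantom generators with full ground-truth
    distortion records, and quantitative evaluation utilities such as
    the relative-similarity measure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
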