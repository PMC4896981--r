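# serialrecon

Reconstructing a 3D image from ordered 2D serial sections is a standard,
and standardly painful, task in histology-based neuroimaging: each section
is imaged on its own, so the stack has lost 3D coherence, every section
carries its own rigid mounting offset and nonlinear tissue distortion, and
naive neighbor-by-neighbor alignment accumulates errors — a curved
specimen reconstructs as a straight one (the "banana effect") and the
stack drifts along the cutting axis (z-shift).

`serialrecon` is an R toolkit of composable reconstruction workflows for
this problem, validated end to end on synthetic phantoms with retained
ground truth:

* **Graph-based sequential alignment** (`reconstruct_graphseq()`): every
  section is registered to its ε-neighborhood; edges are weighted by
  `w = (1 + s)·Δ^λ + η`, where `s ∈ [−1, 0]` is the rescaled
  cross-correlation after alignment and Δ the index distance; per-section
  transforms are composed along least-cost (Dijkstra) chains from a
  reference section.  Heavily distorted sections attract expensive edges
  and are bypassed — and thereby detected.
* **Iterative pairwise alignment to a shape prior**
  (`iterative_pairwise()`): alternates a global 3D affine registration of
  a reference volume (MRI, blockface) to the current reconstruction with
  per-section 2D registrations to the matching *virtual cuts* of the
  reference; handles sections cut obliquely to the reference planes.
* **Coarse-to-fine merging** (`coarse_to_fine()`): combines a
  reference-aligned (coarse) rigid series with the high-frequency
  component of a sequential (fine) rigid series,
  `merged = coarse + (fine − G_σ ⋆ fine)` per parameter channel, removing
  z-shift while preserving section-to-section coherence.
* **Deformable refinement** (`deformable_reconstruct()`): each section is
  deformably registered to the average of its ε-neighborhood, iterated;
  the per-iteration history (consecutive-difference MSQ, and relative
  similarity `S = MSQ(R, B)/MSQ(R, D)` when ground truth is available)
  locates the optimal stop before the stack over-smooths.

Under these workflows sits an in-house intensity-based registration
engine (`register_rigid2d()`, `register_affine2d()`, `register_affine3d()`,
`register_deformable2d()`) with MSQ / cross-correlation / mutual-information
metrics, multi-resolution derivative-free optimization, and a
Gaussian-regularized demons-style deformable model — plus NIfTI I/O
(`read_nifti_image()`, `write_stack_sections()`), an explicit transform
algebra (`t_compose()`, `t_invert()`, `rigid_recenter()`), and seeded
phantom/distortion generators (`make_banana_phantom()`,
`make_layered_phantom()`, `distort_rigid()`, `ablate_sections()`,
`make_displacement_distortion()`) that return full ground-truth records.

## Worked example

Distort a synthetic curved-tube phantom with per-section rigid offsets
(σ = 10 mm translation, σ = 10° rotation), then reconstruct with the
coarse-to-fine workflow using the undistorted volume as shape prior:

```r
library(serialrecon)

truth <- volume_to_stack(make_banana_phantom(
  n_slices = 100, thickness = 2, inplane_dim = c(80, 80),
  inplane_spacing = c(2, 2)))
distorted <- distort_rigid(truth, sigma_t = 10, sigma_theta = 10, seed = 21)

cf <- coarse_to_fine(distorted$stack, truth, fine_method = "naive",
                     sigma_z = 5, truth = truth)
cf$report[c("msq_coarse", "msq_fine", "msq_merged")]
```

```
$msq_coarse
[1] 177.3

$msq_fine
[1] 444.1

$msq_merged
[1] 72.6
```

The fine-only (naive sequential) reconstruction is far from the truth —
it has straightened the curve and drifted — the coarse-only
reconstruction recovers the global shape but leaves per-section jitter,
and the merged series is better than either: the global trend comes from
the coarse series, the section-to-section detail from the fine one.
(Exact values depend on the seed; these are from the run above.)

Deformable refinement of nonlinearly distorted sections:

```r
truth <- volume_to_stack(make_layered_phantom(n_sections = 40))
dist  <- distort_displacement(truth, kernel_sigma = 0.3,
                              target_median = 0.05, seed = 11)
rec <- deformable_reconstruct(dist$stack, epsilon = 1, n_iter = 10,
                              reference = truth)
S <- rec$report$msq_to_ref /
     msq(stack_to_volume(truth), stack_to_volume(dist$stack))
round(S, 2)
#>  [1] 0.68 0.64 0.68 0.71 0.76 0.80 0.85 0.90 0.95 1.00
```

Relative similarity drops below 0.7 within two iterations and then rises
again as the reconstruction over-smooths — the retained history is what
lets you pick the optimum.

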