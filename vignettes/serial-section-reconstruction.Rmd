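---
title: "Reconstructing 3D volumes from serial sections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D volumes from serial sections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models implemented in `serialrecon`, the
assumptions behind them, the parameters that matter, and the numerical
choices made where the design was genuinely open.  It states no empirical
result that the package's test suite does not itself compute.

## The problem

Serial sectioning destroys 3D coherence: each 2D section is imaged in its
own coordinate frame, with a random rigid offset from mounting and a
smooth nonlinear distortion from cutting, stretching and staining.  All
workflows here assume the sections are **ordered** and of **constant
thickness**; re-ordering and variable thickness are out of scope.

Two failure modes dominate naive neighbor-by-neighbor alignment:

* **Error propagation** — pairwise registration errors compose along the
  chain, so remote sections drift (z-shift).
* **Shape loss** — aligning each section to its neighbor is blind to the
  true 3D shape; curvature along the cutting axis is flattened out (the
  "banana effect").  Only an external shape prior (an MRI, blockface
  photographs, an atlas) can restore it.

## Image and transform model

Images are physically addressed: pixel `(i, j)` of a `planar_image` sits
at `origin + (i-1, j-1) * spacing` (mm), and the default origin centers
the grid on `(0, 0)`, so rotations about the physical origin are
rotations about the image center.  All transforms are **pull-back** maps:
resampling an image through `t` computes `out(p) = in(t(p))`, i.e. `t`
maps output coordinates to input coordinates.  A single convention
everywhere prevents the inverse confusion that otherwise creeps in when
transform chains from different workflows are composed; the price — that
"moving section j onto section i" is represented by a map from i's frame
to j's frame — is paid once, in documentation.

Rigid 2D transforms are parameterized as (angle in degrees, translation
in mm, pivot); angles are wrapped to (−180°, 180°], and transform series
are unwrapped along the stack before any parameter-space smoothing
(smoothing across a ±180° wrap would corrupt the lowpass).  Composition
and inversion are exact affine algebra; `compose(t, t⁻¹)` is the identity
to 1e−9 (property-tested over random transforms).

## The registration engine

The engine is intensity-based multi-resolution optimization:

* **Metrics.** Mean squared intensity difference
  `MSQ(A,B) = (1/N) Σᵢ (Aᵢ−Bᵢ)²`; normalized cross-correlation (Pearson),
  rescaled for graph edge weights to `s = −(1+NCC)/2 ∈ [−1, 0]` so that
  lower means more similar; and mutual information from a 32-bin joint
  histogram on min-max-normalized intensities (natural log).  The MI bin
  count and the CC rescaling map are engine-level choices: the histogram
  binning is the standard Mattes-style coarse binning and is
  deterministic; the rescaling is the affine map onto the stated target
  interval.
* **Optimizer.** Nelder–Mead on normalized parameters (rotations in
  degrees, translations in pixels, log-scales and shears dimensionless),
  coarse-to-fine over a dyadic image pyramid.  Derivative-free
  optimization is robust for MI, whose histogram gradient is awkward.
  Rigid 2D uses multi-start over initial rotations (±10° by default) at
  the coarsest level; 3D registration initializes translation from the
  intensity centroids and searches a small per-axis rotation grid (±10°)
  at the coarsest level before descending.
* **Interpolation-bias control.**  Two measures that matter numerically:
  (1) metric evaluations resample with Catmull–Rom cubic interpolation
  and both pyramid levels are pre-smoothed by 1.5 px, because linear
  interpolation's spatially varying smoothing otherwise *biases the
  optimum toward grid-aligned transforms* (on smooth phantoms the bias
  reaches a degree of rotation); (2) in 3D the metric is sampled on a
  half-voxel-offset grid so the fixed volume is interpolated exactly like
  the moving one — without this, transforms that sample the volume
  exactly on its slice planes enjoy a blur-free advantage that walls off
  the optimizer along the z-related parameters.
* **Deformable model.**  Gaussian-regularized demons-style iteration
  rather than a full symmetric-normalization method: the update force is
  the classic normalized intensity-difference force, scaled by
  `gradient_step`, smoothed with `sigma_update` (fluid-like), composed
  into the accumulated field, which is then smoothed with `sigma_total`
  (elastic-like); both sigmas default to one pixel.  The engine keeps the
  best-scoring field, so the returned warp never scores worse than the
  identity.  The workflows rely only on this contract (monotone metric,
  smoothness under the sigmas), not on any specific transformation model.

Known limitation: recovered fields are accurate only where the images
have intensity gradients; in flat regions the regularization pulls the
field toward zero, which is why engine-level field-recovery tests use
fully textured images, and why reconstruction quality is assessed on
image similarity rather than field residuals.

## Graph-based sequential alignment

Every section is registered to its ε-neighborhood (`1 ≤ |i−j| ≤ ε`), and
an undirected weighted graph is built with edge weight

    w = (1 + s) · Δ^λ + η,      η = 1e−6

where `s` is the rescaled NCC after alignment and Δ the index distance.
Per-section transforms are composed along the least-cost path from a
reference section (Dijkstra; ties broken by fewer hops, then
lexicographically smallest path, so results are deterministic).  The
weight formula is a design choice satisfying the method's qualitative
contract: at λ = 0 the multiplier is flat in Δ, so paths are free to jump
over expensive (badly distorted) sections; larger λ penalizes long jumps
and preserves sections.  The η floor avoids zero-weight tie pathologies
between perfectly similar pairs.

Sections are flagged as *standing out* when they serve as an intermediate
vertex in no chain; the reference and the two stack-end sections are
excluded from flagging since they can never be intermediates.  This is a
concrete proxy for visual annotation of skipped sections and is
documented as a heuristic.  Two structural facts worth knowing: a run of
k consecutive distorted sections can only be fully bypassed when
ε ≥ k + 1 (the bypass needs a distance-(k+1) edge), and any chain that
crosses a not-fully-bypassable run must use at least one run member as an
intermediate — so such runs are detected member-by-member, never all at
once.

For section skipping to stay *selective* at λ = 0, the similarity decay
of clean neighbors must grow superlinearly with Δ (two short hops then
cost less than one long jump).  Smooth, band-limited images behave this
way; images with hard (aliased) edges decay linearly and tip the balance
toward indiscriminate jumping.  This is a property of the data, not of
the algorithm — the phantom generator therefore produces band-limited
rims (see below).

## Pairwise alignment to a shape prior

Algorithmically: per iteration (1) the current sections are stacked into
a volume; (2) the reference volume (moving) is affinely registered to
that stack volume (fixed), refining a cumulative 3D affine — this
direction means the experimental sections are never resampled through
the 3D map; (3) the reference is resliced through the cumulative
transform into one *virtual cut* per section; (4) every **original**
section is re-registered (rigid by default, affine optional) to its
virtual cut, transforms being **replaced, not chained**, which prevents
interpolation blur from accumulating across iterations.  Virtual cuts are
a pure function of (reference, transform, grid) and bit-reproducible.

The iteration converges in practice to an approximate fixed point
(re-running from a converged state moves transforms by well under a
tenth of a pixel); the mean parameter change per iteration is recorded
and an optional tolerance (default 0.05 px) stops early.  The default
iteration cap is 10.  Convergence is a trend, not a theorem — the
recorded history is the diagnostic.

## Coarse-to-fine merging

Two rigid series are combined in parameter space (common image-center
pivot, angles unwrapped):

    merged_i = coarse_i + (fine_i − (G_σz ⋆ fine)_i)

The coarse series (per-section registration to the reference cuts)
contributes the global trend — shape, z-position — while the fine series
contributes high-frequency section-to-section detail.  σ_z defaults to
5 sections, applied to rotation and translation channels alike; boundary
handling is reflect padding (nearest is available), a choice the method
leaves open.

One subtlety is essential: **the fine series is computed on the
coarse-aligned stack.**  Both series estimate the same per-section
distortions; if the fine series were computed independently on the raw
stack, its high-frequency component would duplicate the correction the
coarse series already applied, and the merge would apply it twice.
Computed on the coarse output, the fine highpass is exactly the residual
coherence correction.  A corollary of the merge model is a division of
labor: the coarse stage is a quick, single-start global alignment (its
per-section jitter is what the fine stage removes), and the workflow's
default coarse budget is deliberately modest, while the fine stage —
registering nearly identical neighbors at small offsets — runs at full
precision.  The merge algebra itself is exact to 1e−12 per channel and
each original section is interpolated exactly once for the final stack.

## Deformable refinement

Each section `M_i` is deformably registered to the pixel-wise average of
its ε-neighborhood (section i itself excluded — including it biases the
target toward no update; the divisor is the actual neighbor count at the
stack boundaries).  All targets are computed from the current stack
before any section updates (Jacobi ordering: order-independent and
parallelizable, unlike Gauss–Seidel).  Update fields are composed (not
added) into each section's accumulated total field, the total is
re-smoothed with `sigma_total`, and the output sections are the
**original** sections warped once through the accumulated fields.
Averaging uses the *current* (warped) sections, consistent with
iterative refinement.  Per-iteration settings may be supplied as a
schedule.

With unlimited iterations the stack over-smooths and drifts away from
the true anatomy, so the report retains the full history: the
consecutive-difference MSQ between successive reconstructions and, when
a reference is supplied, the per-iteration relative similarity

    S = MSQ(R, B) / MSQ(R, D)

(iteration 0 is the distorted input, S = 1; S < 1 is improvement; S is
invariant under common intensity rescaling).  Stop modes: a fixed
iteration count, a threshold on the consecutive difference, or the first
local minimum of that curve.  The optimal neighborhood radius and
iteration count are selected as the argmin of the mean relative
similarity over trials (ties resolved toward the smaller parameter).

## Synthetic data: what it emulates, and what not

The generators reproduce the study conditions of the validation
experiments, with full provenance (parameters, seeds, per-section
ground-truth transforms or fields) attached to every output:

* `make_banana_phantom()` — a curved elliptical tube with a smooth
  internal gradient and seeded low-frequency texture, the texture being a
  sum of random-frequency cosines evaluated in *physical* coordinates
  (grid-independent, so re-slicing at another thickness samples the same
  object).  The rim falls off smoothly over ~2–3 pixels: real MR images
  are band-limited, and a hard rim would make neighbor similarity decay
  linearly with index distance, distorting the graph method's
  skip/preserve balance (see above).  Defaults: 200 slices, 80×80 pixels
  at 2 mm in-plane, 1 mm thickness, radius 15 mm, sagitta 40 % of the
  half-length.
* `distort_rigid()` — independent zero-mean Gaussian rigid offsets per
  section, σ = 10 mm per translation axis and σ = 10° rotation by
  default, applied about the section centers with cubic interpolation.
* `ablate_sections()` — removes a seeded random half-plane containing a
  given fraction (default one half) of a section's foreground, the cut
  offset being the exact projection quantile; emulates severely damaged
  sections, including consecutive runs.
* `make_displacement_distortion()` — per-component white noise smoothed
  with a Gaussian kernel (default σ = 300 μm), each component rescaled to
  [−r, r] with `r` from `calibrate_amplitude()`, which is exact linear
  scaling: the median displacement magnitude equals the target (default
  50 μm) to floating-point accuracy.
* `make_layered_phantom()` — nested ellipsoidal shells of distinct
  intensities plus a curved internal rod, evaluated analytically in
  physical space; defaults 40 sections of 48×48 pixels at 50 μm.

What passing tests on these phantoms do **not** show: robustness to
stain inhomogeneity, tears and folds, missing sections, or multi-modal
intensity relationships — none of which the generators model.  The
phantoms establish that the geometry of each workflow is correct and
that the engine recovers the stated distortion scales.

## Problem sizes and numerical choices

The validation experiments in the test suite run at desk scale, chosen
once: the coarse-to-fine experiment uses a 100-slice banana at 80×80 ×
2 mm; the graph experiment 60 sections with ablated runs of lengths 3
and 2 (the graph input is generated as a straight tube, mirroring the
original experiment's use of an already-sequentially-aligned volume —
with a curved input the pairwise "ground truth" between neighboring
sections is confounded by the centroid drift that *is* the banana
effect); the deformable benchmark sweeps ε ∈ {1, 2, 3} over three seeds
on a 40-section layered phantom with 300 μm / 50 μm calibrated warps,
10 iterations each, at the engine's default demons budget (20
iterations on each of two levels).
Registration budgets are engine parameters, not fidelity claims; the
recovery tolerances the engine is tested at (rigid 2D: 0.5 mm / 0.5° on
±10 mm / ±10° perturbations; affine 3D: 1.5° on a 10° oblique rotation)
are met at these sizes.

Degenerate inputs are handled explicitly: zero-variance images make NCC
undefined (error) and MI zero (warning); flat images give a zero
deformable field with a warning; failed pair registrations enter the
graph with worst-case similarity and identity transforms, flagged;
failed per-section registrations in the coarse series fall back to the
identity, flagged; a disconnected graph vertex and a reference volume
with no overlap are errors naming the offender.

## Known limitations

* Rigid and affine models assume in-plane distortions; out-of-plane
  (oblique) effects are handled only by the 3D stage of the pairwise
  workflow.
* The deformable stage regularizes strictly within sections (2D); no 3D
  coherence is imposed on the fields.
* The flagging rule is a structural heuristic; it cannot mark every
  member of a distorted run unless the run is fully bypassable
  (ε ≥ run length + 1).
* Engine accuracy degrades with image smoothness: a featureless blob
  constrains rotation weakly, and no optimizer can fix an
  ill-conditioned metric.
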