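---
title: "Surface morphometry of hippocampal subfields: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface morphometry of hippocampal subfields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomorph)
```

## The scientific problem

Progression from mild cognitive impairment (MCI) to Alzheimer's disease is
accompanied by atrophy and structural remodelling of the hippocampus that is
not uniform across its subfields. Volumetry alone captures the atrophy but
not the change in surface *shape* — flattening of folds, blurring of subfield
boundaries. `hippomorph` implements a surface-based pipeline that quantifies
both: each subfield mask from a labelled segmentation (e.g. FreeSurfer's
12-subfield parcellation) is reconstructed as a closed triangle surface,
smoothed, and summarized by five indices — volume, surface area, mean maximal
and minimal principal curvature, and the mean **ratio of principal
curvatures (RPC)** — whose longitudinal change rates feed a feature-selection
stage and a small multilayer perceptron (MLP) that classifies converters
versus non-converters.

Of the 12 subfields (parasubiculum, presubiculum, subiculum, CA1, CA3, CA4,
GC-ML-DG, HATA, fimbria, molecular layer, hippocampal fissure, hippocampal
tail), three — parasubiculum, HATA, fimbria — are too small to be measured
reliably at typical MRI resolution and are excluded, leaving 9 analyzed
regions and a 45-feature inventory (9 regions × 5 indices).

## Discrete curvature model

On a closed, oriented triangle mesh the package uses two classical discrete
estimators, computed per vertex \(v\):

* **Gaussian curvature** from the Gauss–Bonnet angle deficit,
  \(K(v) = 2\pi - \sum_i \beta_i\), where the \(\beta_i\) are the interior
  angles of the triangles incident to \(v\). Summed over any closed genus-0
  mesh this is exactly \(4\pi\) (Descartes), which every fixture in the test
  suite verifies to 1e-9.
* **Mean curvature** from edge dihedral angles,
  accumulating \(s(e)\,\psi(e)\) over the edges \(e\) incident to \(v\),
  with \(s(e)\) the edge length and \(\psi(e)\) the *signed* dihedral angle,
  positive where the surface is convex with respect to the outward normal.
  The sign is essential: it is what distinguishes ridges from valleys
  downstream.

Two modes are exposed. `as_written` reproduces the defining formulas
verbatim: \(K\) is the raw deficit (radians) and
\(H(v) = \tfrac1N \sum_e s(e)\psi(e)\) (mm·radians). These are dimensionally
inhomogeneous — integrated, not pointwise, quantities — but they are the
published operators, so they remain the default for fidelity.
`area_normalized` provides the dimensionally consistent pointwise
estimators used by all analytic-oracle tests: \(K(v)\) divided by the
barycentric vertex area \(A_v\) (one third of incident triangle area, units
mm⁻²) and \(H(v) = \sum_e s(e)\psi(e) / (4 A_v)\) (mm⁻¹), the standard
cotangent-free edge formula. On an icosphere of radius 10 mm these recover
\(1/r^2 = 0.01\) mm⁻² and \(1/r = 0.1\) mm⁻¹ within a fraction of a percent:

```{r icosphere}
ico <- icosphereMesh(10, 4)
cf <- curvatureField(ico, mode = "area_normalized")
cf
```

A note on the `as_written` mean-curvature normalization: the defining
per-vertex expression divides by the 1-ring size \(N\). Dividing the same
sum *additionally* by \(4A_v\) would mix the two conventions and be off from
the standard estimator by a factor of roughly \(N\); `area_normalized`
therefore replaces (not augments) the \(1/N\) with \(1/(4A_v)\).

**Principal curvatures and RPC.** The principal curvatures are the roots
\(c_{max} = H + \sqrt{H^2 - K}\), \(c_{min} = H - \sqrt{H^2 - K}\). (A sign
typo is common in print — both roots written with "+" — but that would make
\(c_{max} \equiv c_{min}\) and the ratio identically 1; the subtracted root
is the only reading consistent with distinct folding patterns.) For
discrete estimates the discriminant \(H^2 - K\) can be slightly negative;
it is clamped to zero, the vertex treated as umbilic, and the number of
clamped vertices reported (`clampCount`). The folding biomarker is

\[ RPC = \frac{\max(|c_{max}|, |c_{min}|)}{\min(|c_{max}|, |c_{min}|)} \ge 1, \]

equal to 1 at umbilic (locally spherical) points and large on ridge- or
valley-like folds where one principal curvature is near zero. The
denominator is floored at `eps = 1e-8` (configurable), so a perfectly
parabolic vertex yields RPC = 1e8 rather than infinity.

**Numerical behaviour of RPC near umbilic points.** Because
\(\sqrt{H^2-K}\) has infinite slope at \(H^2 = K\), small estimation noise
in \(K\) and \(H\) is *amplified* into RPC on nearly-spherical surfaces: a
voxel-reconstructed sphere whose \(K\) and \(H\) are each within a few
percent of truth still shows a mean vertex RPC above 2. This is a property
of the ratio itself, not of the estimators; it is why per-region summaries
use the *mean* RPC (comparable within a protocol but not an absolute
umbilicity measure), and why an optional 99th-percentile winsorization of
RPC is provided (off by default) for sensitivity analyses. On a near-exact
triangulation (the icosphere) the median RPC is 1, as theory requires. RPC
is exactly invariant to global rescaling of the surface in
`area_normalized` mode; in `as_written` mode it is not, because the raw
\(K\) and \(H\) carry different units.

**Folding classes.** Thresholding \((c_{max}, c_{min})\) at \(\tau\) gives
six exhaustive local patterns (cap, ridge, flat, valley, cup, saddle).
No published value of \(\tau\) exists, so the default is the 25th
percentile of \(|c|\) pooled over both principal curvatures of the surface
being classified; the value actually used is always recorded in the
returned histogram.

## Surface reconstruction and smoothing

Masks are extracted per region (or as the union of all 12 labels for the
whole hippocampus) and the 0.5 iso-surface is triangulated by a tetrahedral
decomposition of each grid cell — the *marching-tetrahedra* variant of
marching cubes, chosen because the classic 256-case cube table contains
ambiguous configurations that can produce non-manifold surfaces, whereas
the 6-tetrahedra decomposition (all sharing the cell's main diagonal, so
face diagonals agree between neighbouring cells) is guaranteed to produce a
closed, edge-manifold, consistently outward-oriented surface. Every
reconstruction passes `checkMesh()`; the curvature operators require it.
Triangle orientation is fixed constructively: each emitted triangle's
normal points away from the inside corners of its tetrahedron. Only the
largest connected component is retained (speckle from segmentation noise is
discarded). Voxel index \((i,j,k)\) maps to \(((i{-}1)s_x, (j{-}1)s_y,
(k{-}1)s_z)\) mm; NIfTI orientation matrices beyond voxel spacing are
deliberately out of scope.

Smoothing is umbrella (uniform-weight) Laplacian relaxation: 50 iterations
by default, each moving a vertex halfway (`step = 0.5`) toward its 1-ring
mean. Pure umbrella smoothing contracts a closed surface without bound, at
a rate set by the local edge length — so the measured area of a smoothed
region would depend on mesh resolution, not anatomy. Each pass therefore
ends with a uniform rescale about the centroid restoring the enclosed
volume (the convention of mainstream mesh-processing toolkits). Staircase
artefacts are still removed — the surface converges toward the
minimal-area shape at fixed volume — but the systematic shrinkage is gone:
the rasterized 10 mm sphere's area lands within 1% of \(4\pi r^2\) after 50
iterations instead of 8–20% low. The uncompensated operator remains
available (`volumeConstraint = FALSE`), as does Taubin \(\lambda/\mu\)
band-pass smoothing (`taubin = TRUE`, off by default).

The *volume* feature is voxel count × voxel volume (segmentation
volumetry convention); the enclosed mesh volume is computed as well but
used for geometric validation only.

## Registration and label transfer

Subfield surfaces are related to the smoothed whole-hippocampus surface by
point-to-point ICP: nearest-neighbour correspondences alternate with
closed-form (SVD/Kabsch) rigid updates, initialized by centroid alignment
(a raw identity start can be trapped by a large translation offset), until
the RMS residual change falls below `tol`. The RMS sequence is
non-increasing; a known rigid displacement (10° rotation, arbitrary
translation) is recovered to machine precision on clean correspondence
structure. Label transfer then assigns every whole-surface vertex the name
of its nearest registered subfield vertex, with deterministic tie-breaking
(lowest vertex index within a region, lexicographic region order across
regions). The transfer direction — subfields onto the smoothed whole
surface — is a design choice; the alternative direction is equivalent for
the per-region summaries used here.

## Change rates and group statistics

Longitudinal change of an index \(f\) between two visits is
\(C_f = (f_{second} - f_{first}) / f_{second}\) — note the *second*-visit
denominator, implemented exactly as defined (the quantity is therefore not
antisymmetric under visit exchange). Change rates are fractions internally
and percentages in reports. Group comparisons use the pooled-variance
two-sample t-test (Welch optional), absolute Cohen's
\(d = |m_1 - m_2| / \sqrt{(s_1^2+s_2^2)/2}\) (equal-n pooled SD, matching
the always-positive published effect-size columns), Pearson chi-square with
Yates continuity correction for 2×2 demographic tables (the published
gender statistic of 0 is only reproducible with the correction), and
Pearson correlation. Recomputing Cohen's d from the published rounded group
summaries reproduces the published d column to 2 decimals for 25 of 27
rows; the two exceptions differ by ≤ 0.006, exactly the propagation of the
2-decimal rounding of the inputs. No multiple-comparison correction is
applied (raw p-values are reported, following the published analysis).

## Synthetic data: what it emulates and what it does not

Two generators make the pipeline testable end to end without clinical data.

`rasterizeShape()` voxelizes spheres, ellipsoids, tori and two-lobe shapes
by center-inclusion (a voxel is foreground iff its centre is strictly
inside the analytic surface), the simplest rule for which the voxel-count
volume oracle is exact up to boundary terms; counts converge to analytic
volumes as spacing shrinks. These stand in for subfield masks of known
geometry.

`simulateCohort()` draws two groups of `nPerGroup = 89` subjects (the
study's group size) with each of the 45 change-rate features Gaussian at
its group's published mean and SD (in percent). The published record
provides marginals for volume, surface-area and RPC change in all 9
regions (27 features). For the 18 curvature-extremum features it provides
only univariate p-values for 8; for those the generator back-derives the
effect size (\(|t| = q_t(1-p/2, 176)\), \(d = |t|/\sqrt{89/2}\)) and
expresses it as a converter-group mean shift of \(d \times 8\) percentage
points about a stable-group mean of 0 with SD 8% — an SD chosen once as
comparable to the published RPC-change SDs. The 10 curvature features with
no published statistic are null (d = 0). Features are independent by
default because no covariances are published; an optional equicorrelation
(`correlation`) adds a per-subject common factor. Group labels are 0 =
non-converter, 1 = converter (the positive class throughout). Each
(group, feature) pair draws from its own deterministic sub-stream of the
root seed, so extending the feature list never perturbs existing columns.

What the synthetic cohort *cannot* emulate: the real joint distribution
(correlated atrophy across neighbouring subfields), non-Gaussian tails,
segmentation error, and any subject-level link between geometry and label
beyond the published marginals. Passing model tests therefore demonstrate
that the selection and classification machinery behaves correctly under
the published effect-size structure — an accuracy close to the published
one on this cohort is a consistency check, not a reproduction of the
clinical result.

## Feature selection and the MLP

Univariate selection ranks features by two-sample t-test p-value and keeps
those below a threshold (strict `<`); on the published 30-feature ranking
the thresholds 0.01 / 0.05 / 0.1 select 19 / 21 / 25 features, matching
the published counts. Forest selection fits 100 random forests of 20 trees
and ranks features by Gini importance summed across forests; each forest's
importances are normalized to sum to 1 before summation so no single
forest dominates (the published description of the cross-forest weighting
is ambiguous; normalized summation is this package's documented choice).

The classifier is an MLP with two 12-neuron ReLU hidden layers and a
sigmoid output, trained by full-batch Adam (momentum 0.9, adaptive
per-parameter learning rate, base rate 1e-3), L2 penalty 1e-4, for a fixed
budget of 800 iterations. Each of (by default) 100 repeats shuffles the
cohort, makes a *stratified* 60/30/10 train/test/validation split
(stratification avoids degenerate single-class test splits at n = 178; the
published protocol says only "randomly shuffled"), standardizes features
with train-split statistics (a recorded deviation: ReLU networks on
percent-scale inputs need it), trains, and scores the *test* split only.
The 10% validation split is held out and can drive optional early stopping
(`earlyStopping = TRUE`), which is off by default so training matches the
fixed-iteration-budget protocol. Sensitivity is converter recall,
specificity non-converter recall; an undefined metric (no positives in the
truth) is returned as `NA` with a warning, never silently 0. The engine is
written in-package because no installed R package offers this architecture
(single-hidden-layer logistic networks are the closest available).

On the default synthetic cohort, the top-20 forest-selected features give
a repeat-averaged test accuracy of roughly 80–84% across seeds — of the
same order as the published 79.95%, with the caveat of the previous
section.

## Problem sizes and numerical choices

The test and acceptance workloads use: sphere fixtures of radius 10 mm at
1 mm spacing (~4,100 voxels, ~5,600 vertices), icosphere subdivision 4
(2,562 vertices), cohorts of 89 + 89 subjects, 100 random forests × 20
trees, MLP repeats of 10–100, and 100-seed recovery experiments with 5
forests per seed — sizes chosen so the full pipeline exercises every code
path while each suite completes in minutes on one core. Other fixed
choices: iso-level 0.5 on binary masks; RPC floor 1e-8; clamped negative
discriminants counted and asserted rare (< 20% of vertices on smoothed
reconstructions); ICP tolerance 1e-6 on the RMS change with exact
(re-computed) matched distances to avoid catastrophic cancellation near
convergence; nearest-neighbour and transfer ties broken by index and name
order — determinism over elegance.

## Known limitations

* No affine/orientation handling of NIfTI headers beyond voxel spacing.
* `as_written` curvatures are integrated quantities with mixed units;
  cross-study comparisons should use `area_normalized`.
* Mean RPC on nearly-umbilic surfaces is noise-inflated (see above).
* The synthetic cohort matches published marginals only; classifier
  accuracies on it are not clinical results.
* Point-to-point ICP assumes a good initial overlap (centroid alignment);
  no non-rigid registration is provided.
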