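---
title: "Methods: brainstem internal-structure segmentation from MP2RAGE images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brainstem internal-structure segmentation from MP2RAGE images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bstemseg)
```

## The problem

The human brainstem contains dozens of small gray- and white-matter
structures (periaqueductal gray, raphe nuclei, corticospinal tract, inferior
olive, ...) that conventional whole-brain segmentation treats as a single
block. The MP2RAGE sequence yields two co-registered views of the same
anatomy — a bias-reduced T1-weighted image (UNI: white matter bright, CSF
dark) and a quantitative T1 relaxation map (T1 map: white matter dark, CSF
bright). `bstemseg` segments internal brainstem tissue types from these two
images plus a derived ratio image, without any anatomical atlas of the
structures themselves.

The pipeline has three stages:

1. **Intensity calibration.** Per subject, UNI and T1 map are linearly
   rescaled so that the histogram modes of high-confidence white-matter and
   CSF voxels land on fixed reference intensities, and the quotient of the
   two rescaled images (RATIO) is formed as a third, contrast-amplified
   channel.
2. **First-pass segmentation and priors.** Voxels inside a brainstem mask
   are clustered by k-means (k = 6) on the z-scored channel triplet; the
   per-subject binary cluster maps are aligned by iterative diffeomorphic
   template building, and their group averages become probabilistic priors.
3. **Refinement.** Each voxel's cluster assignment is checked against the
   priors projected back into subject space, reassigned under explicit
   probability rules, and converted to probabilistic maps.

Quality is quantified by a low-silhouette index and a miss-classification
index, and the template-building deformations feed deformation-based
morphometry (DBM).

## Intensity calibration

For the UNI image, with `wm` and `csf` the histogram modes of voxels whose
white-matter or CSF probability exceeds 0.9, the rescaled image is
`UNI_cal = UNI * fact - shift` with

```
fact  = (Ref1 - Ref2) / (wm - csf)
shift = (csf * Ref1 - wm * Ref2) / (wm - csf)
```

so that `wm -> Ref1 = 100` and `csf -> Ref2 = 20` exactly. The T1 map uses
the mirrored assignment (`wm -> Ref2`, `csf -> Ref1`) because its tissue
ordering is inverted. We derived the shift term from the two anchor
identities directly; this reproduces the reported magnitude of the scale
factor (about 0.04 for a typical 3 T UNI with modes near 3000/1000) and
makes both anchors exact by construction, which is the property the
downstream stages rely on.

Details that the anchor identities do not fix, and how we resolved them:

* **Mode estimation.** 256 equal-width bins over the included intensity
  range, argmax bin centre, ties toward the lower bin. Before binning,
  presumed vessel voxels are excluded: intensities above the 95th percentile
  for UNI (vessels bright) and below the 1st percentile for the T1 map
  (vessels dark), each within the tissue's own high-confidence sample.
* **Negative voxels.** The subtraction can push dark voxels negative. They
  are replaced by the mean of their non-negative 6-connected neighbours in a
  single pass over the original values (replacements never feed each other);
  a voxel with no qualifying neighbour becomes 0.
* **RATIO guard and cap.** The denominator is guarded by an epsilon of 1e-6
  times the masked T1map-cal median. RATIO voxels above the 99th percentile
  are replaced by the mean of neighbours at or below it; with no qualifying
  neighbour the voxel is set to the percentile value itself.
* **"First-order neighbourhood"** is read as 6-connectivity in 3-D
  throughout.

## First-pass clustering

Channels are restricted to a brainstem tissue mask (calibrated UNI above 10,
i.e. half the dark anchor — low enough to keep the CSF/tissue boundary
shell, high enough to drop residual near-zero voxels; the cutoff is a
configuration entry). Each channel is z-scored over the mask with the
population (divide-by-n) standard deviation, so the stack has exactly unit
variance per channel.

k-means uses Lloyd iterations with squared Euclidean distance, k-means++
seeding, a configurable number of random restarts (the method's reference
setting is 100; tests and examples use 5-10, which is ample at phantom
separations), and returns the restart with minimal within-cluster sum of
squares. Empty clusters trigger a re-seeded restart rather than a k-1
solution. Because cluster numbering is arbitrary, every subject's centroids
are matched to a designated reference subject by exhaustive minimal-cost
assignment over the 6! permutations; the reference is an explicit argument
rather than a random subject so runs are reproducible.

## Priors by diffeomorphic template building

The six binary maps per subject (plus an implicit background channel,
1 minus their sum, which stabilizes registration at the mask boundary) are
registered jointly to an evolving group average: in each of `n_outer = 3`
iterations, every subject is aligned to the current average by a
stationary-velocity-field registration (demons-style sum-of-squared-
difference forces; Gaussian smoothing of the update with sigma 1.0 voxels
and of the velocity with sigma 1.2 voxels; steps capped and halved once if
the cost rises), and the average of the warped maps becomes the next
template. The velocity-field parameterization gives invertibility by
construction — the transform is the scaling-and-squaring exponential of the
velocity, its inverse the exponential of the negation — and every accepted
transform is checked for a positive Jacobian determinant. The final
averages, clipped to [0, 1], are the priors; the stored inverse
displacements project them back into each subject's space with trilinear
interpolation.

The hyperparameters were chosen for deformations of the magnitude the
cohort model produces (about 1-2 voxels RMS between subjects) and are
exposed in `priors_params()`. With identical input subjects the update
force is zero everywhere, so the identity is an exact fixed point.
Convergence is tracked by the mean registration cost and by an alignment
overlap: the generalized Dice between each subject's warped maps and the
template, with both sides discretized by argmax (background channel
included) so that interpolation softness is not mistaken for misalignment;
an iteration-0 row records the pre-registration baseline. On jittered
cohorts this overlap increases monotonically over the outer iterations.

## Refinement rules

Per-voxel centroid distances are min-max standardized within each cluster
(nearest voxel weight 1, farthest 0; all-equal distances give weight 1). A
voxel whose label disagrees with the argmax of the subject-space priors is
reassigned to that alternate cluster iff the alternate prior is at least
0.75, or exceeds the original cluster's prior by at least 0.20; otherwise it
keeps its label. Prior-argmax ties break toward the lower cluster index.
The final probabilistic maps are `[label = c] * prior_c * weight`, which we
read as the natural meaning of weighting the prior by the standardized
distance; the maps therefore never exceed the warped prior. Weights of
reassigned voxels are recomputed from the distance to the receiving
cluster's centroid, standardized within that cluster's distance range, so
the weight semantics always refer to the final cluster. Refinement is a
single pass, not iterated to a fixed point.

## Quality indices

* **Low-silhouette index**: for every cluster except the partial-volume
  boundary cluster (cluster 2), the percentage of voxels with silhouette
  strictly above 0.6; the index is the mean of the five percentages,
  averaged per subject before any group summary. Silhouettes are the
  classical (b - a)/max(a, b) in z-score space, computed exactly up to a
  cap (default 20,000 voxels, a size a vectorized exact pass handles
  comfortably) and on a seeded subsample above it.
* **Miss-classification index**: per cluster, the percentage of first-pass
  voxels whose own subject-space prior is below 0.3; the index is the mean
  over nonempty clusters. The mean standardized distance weight of the
  miss-classified voxels accompanies it. Per-cluster values are reported so
  an analyst can exclude pathological clusters; the package never drops
  them automatically.

## Deformation-based morphometry

Jacobian determinant maps are computed by central finite differences (one-
sided at the boundary) of the template-to-subject sampling map `x + u(x)`
that lives on the template grid, so a value above 1 means the subject is
locally larger than the template and planted atrophy appears as values
below 1. Group comparison is a voxelwise pooled-variance two-sided t
statistic with family-wise error control by the permutation max-T method
(Westfall-Young order-statistic threshold), which replaces parametric
random-field correction: it makes no smoothness assumptions and is directly
verifiable by simulation at small cohort sizes. Unsmoothed maps are used.

## The phantom: what it emulates and what it does not

`generate_cohort()` renders a stylized head — CSF rim, ventricle,
white-matter bulk, gray-matter matrix — containing a tapered elliptical
"brainstem" cylinder with six internal classes: a gray-matter matrix (1), a
1-2 voxel CSF/tissue boundary shell (2, the partial-volume class), paired
ventral tracts (3), a dorsal periaqueductal-like column (4), and two pairs
of nuclear blobs (5, 6). Class means are laid out along the gray/white
continuum with opposite orderings on the two channels (UNI 1600-3050, T1
map 3000-900 arbitrary units, head CSF 1000/4000, WM 3000/900), additive
Gaussian channel noise (default sd 60 on UNI, 80 on the T1 map — roughly
the class-gap-to-noise ratio of good 3 T data; a Rician option exists), a
smooth multiplicative bias field of relative amplitude 0.05, and smooth
random per-subject warps of 1.5 mm RMS realized as exponentials of
stationary velocity fields (always invertible, with the true forward and
inverse deformations returned). Optional atrophy scales a chosen class's
volume by a factor, applied as a per-connected-component radial contraction
with a smooth taper so the deformation stays local to the structure;
overlapping tapers are renormalized so the combined map remains a pure
scaling.

The phantom reproduces the statistical structure the pipeline depends on —
intensity orderings, a boundary shell, cross-subject geometric variability,
known ground truth — but not anatomy or MR physics: no pulse-sequence
simulation, no realistic brainstem shape, no spatially correlated noise, no
partial-volume averaging beyond the explicit shell class. Passing tests
therefore demonstrate the correctness and internal consistency of the
algorithms under controlled conditions, not segmentation accuracy on real
MP2RAGE data.

## Problem sizes and numerical choices

The shipped tests and examples run the full pipeline on 48 x 56 x 40
phantom grids (about 4,000 brainstem voxels) with cohorts of 2-16 subjects,
10 k-means restarts, 3 template iterations of 12 registration steps, and
500-1,000 permutations for DBM — sizes at which every stage's behaviour is
already asymptotic while a complete run takes tens of seconds. Noteworthy
conventions: histogram-mode ties break low; prior-argmax ties break toward
the lower cluster; silhouette of a singleton-cluster voxel is 0; the
silhouette threshold 0.6 is strict and the prior threshold 0.3 inclusive;
z-scores use the population sd; k-means distances are stored as plain
Euclidean (standardization is min-max within cluster, so squared vs plain
is monotone-equivalent); the vessel-percentile exclusion is applied within
each tissue's high-confidence sample.

## Known limitations

* The registration is single-resolution and tuned to phantom-scale
  deformations; large inter-subject differences (real cohorts are spatially
  normalized before this pipeline) would need a multi-resolution schedule.
* The low-silhouette index depends on the silhouette subsample above the
  exactness cap.
* Preprocessing (bias correction, tissue probability maps, spatial
  normalization) is an input contract: the package validates grids and
  probability sums but does not perform it.
* The miss-classification index measures consistency with the group priors,
  not truth; on phantoms the two coincide closely because ground truth is
  known.
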