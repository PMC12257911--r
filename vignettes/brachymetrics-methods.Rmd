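---
title: "Distance-penalized evaluation of near-to-target OAR segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-penalized evaluation of near-to-target OAR segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachymetrics)
```

## The problem

In high-dose-rate (HDR) cervical brachytherapy, the dose constraint that
drives planning for each organ at risk (OAR) is D2cm³: the minimum dose
received by the organ's most irradiated 2 cm³, which invariably sits
where the organ approaches the high-risk clinical target volume
(CTV_HR). When auto-segmentation models are evaluated with whole-organ
metrics such as the volumetric Dice similarity coefficient (vDSC), a
contour error on the far side of the bladder counts exactly as much as
one abutting the target — even though only the latter perturbs D2cm³.
This package provides the machinery for a geometrically focused
alternative: distance-penalty maps, distance-penalized training losses,
a weighted Dice coefficient (wDSC) that concentrates on near-to-target
accuracy, and a desk-scale dosimetric surrogate to quantify how well
each metric tracks dose-constraint accuracy.

## The distance-penalty map

Photon fluence from a brachytherapy source falls off, to first
approximation, with the inverse square of distance. The package builds a
per-voxel penalty from that law: an exact anisotropic Euclidean distance
transform gives every voxel its distance $R$ in mm to the nearest
CTV_HR voxel (zero inside the target), and the penalty is the normalized
inverse square

$$ D(v) = \left( \frac{r_\min}{\max(R(v),\, r_\min)} \right)^{2} \in (0, 1]. $$

$1/R^2$ diverges at $R = 0$, so $R$ is clamped below at `r_min` before
inversion; after dividing by the resulting maximum the target carries
penalty exactly 1. The default `r_min` is the smallest voxel spacing —
the finest distance the grid can resolve — and the clamp is this
package's explicit choice for the otherwise-undefined target interior.
Distances are centre-to-centre in physical mm on the anisotropic grid;
orientation beyond voxel spacing is deliberately ignored, since every
quantity here depends only on relative distances.

## Distance-penalized losses

Reference implementations (plain array computations with analytic
gradients) are provided for cross-entropy (CE), pooled soft Dice, their
sum (DiceCE), and the distance-penalized variants DPCE and DPDiceCE, in
which the error terms are weighted voxel-wise by $D$:

$$ L_{DPCE} = -\frac{1}{N} \sum_c \sum_i D_i\, g_{ic} \log p_{ic}, \qquad
   L_{DPDiceCE} = 1 - \frac{2 \sum_c \sum_i D_i\, g_{ic} p_{ic}}
   {\sum_c \sum_i g_{ic} + \sum_c \sum_i p_{ic}} + L_{CE}. $$

Three choices deserve notice. First, the same target-derived map $D$ is
applied to every class: the penalty expresses *where* errors matter,
not *which* organ made them. Second, the trailing CE term of DPDiceCE
is left unweighted, exactly as the combo is defined; a port that
penalizes it too would change the loss surface. Third, the background
class participates in all sums (a `foreground_only` flag exists for
ports to frameworks that exclude it). With $D \equiv 1$ both DP losses
reduce bit-for-bit to their base losses, and for any $D \in [0,1]$,
DPCE $\le$ CE while DPDiceCE $\ge$ DiceCE (the weighted numerator can
only lose overlap credit); both orderings are enforced by tests.
Probabilities are clamped at $\varepsilon = 10^{-7}$ before logs so
one-hot predictions stay finite. The analytic gradients match central
finite differences to $10^{-5}$, the contract any training-framework
port must satisfy.

## The weighted Dice coefficient

wDSC scores a ground-truth/prediction pair through $N$ distance-based
crops. With $R_{\max}$ the largest distance on the grid, crop $i$ keeps
the voxels with $R \le c_i$, $c_i = R_{\max}(N - i + 1)/N$ (and
$c_1 = \infty$, so the outermost crop is the whole grid), and carries
weight $w_i = i/N$: from the boundary toward the centre the weights are
$1/N, 2/N, \dots, 1$. The aggregate is

$$ wDSC = 1 - \frac{1}{N} \sum_{i=1}^{N} w_i \,(1 - vDSC_i). $$

With the default $N = 100$ each increment of the field of view is thin
enough for the weighting to act continuously in distance. A
four-crop illustration: weights $(0.25, 0.5, 0.75, 1)$ outermost to
innermost; if the weight-0.75 crop scores a cropped vDSC of 0.8 and all
others are perfect, the weighted loss is $0.75 \times 0.2 = 0.15$ and
$wDSC = 1 - 0.15/4 = 0.9625$.

Design decisions that the definition leaves open, and how this package
resolves them:

* **Nested crops, not disjoint shells.** "Cropping from the outer
  boundary toward the centre" is read as progressively restricting the
  field of view, so crop $i$ is cumulative: $\{R \le c_i\}$. A
  disjoint-shell variant (`shells = TRUE`) is provided for sensitivity
  analysis; under it each thin shell is scored independently, which
  makes the per-crop values noisier on coarse grids.
* **Thresholds equally spaced in distance,** not in penalty value.
  Equal bins of the inverse-square value would collapse nearly the
  whole grid into one bin because the penalty decays so fast.
* **$R_{\max}$ over the whole grid,** so the scheme depends only on the
  case, never on the prediction, and no false positive can escape all
  crops.
* **Empty-crop conventions.** A crop where neither restricted mask has
  voxels holds no discrepancy and scores 1; a crop where exactly one is
  empty scores 0. wDSC is computed per organ on binary masks.

The property that motivates the metric: for two predictions with the
same error volume — hence identical vDSC — the one whose errors sit
closer to the target scores strictly lower wDSC, mirroring its larger
D2cm³ impact.

## Standard metrics

vDSC, 95th-percentile Hausdorff distance (HD95), surface Dice at 1 mm
tolerance (sDSC), added path length (APL), and average symmetric
surface distance (ASSD) complete the evaluation panel. Surfaces are
represented as boundary faces between foreground and background (or
out-of-grid) voxels, each face carrying its physical area, so distance
distributions are area-weighted on anisotropic grids. Numerical
details: the HD95 percentile is a midpoint-cumulative linear
interpolation of the area-weighted distance distribution, with tied
distances merged first so the result is independent of face enumeration
order; HD95 symmetrizes as the maximum of the two directed percentiles;
APL is computed slice-wise in 2D (axial), counting 8-connected contour
pixels of the ground truth absent from the prediction's contour, scaled
by mean in-plane spacing, and reported in cm (4- vs 8-connectivity is
not settled by the definition; 8 is this package's documented choice).
When exactly one mask is empty, the bounded metrics degrade to 0, APL
to the full ground-truth contour length, and the distance metrics are
reported missing, because they are genuinely undefined.

## The dose surrogate

Clinical D2cm³ values come from a treatment-planning system with
applicator reconstruction — out of reach at desk scale. The package
substitutes a transparent engine that keeps the *physics that makes
D2cm³ distance-sensitive*: point-source dwells placed along the
target's axis, each contributing `strength / max(r, r_clamp)²` Gy by
superposition. No anisotropy or radial dose functions are modelled, so
absolute clinical dose tables are explicitly out of reproduction scope;
what the surrogate preserves is that organ dose is dominated by the
near-to-target surface, which is all the correlation analysis needs.
D2cm³ is extracted at voxel resolution (sort doses, accumulate voxel
volumes to 2 cm³) with no sub-voxel interpolation — deterministic and
oracle-testable, and phantom voxels (3 mm³) are small relative to
2 cm³. Organs smaller than 2 cm³ fall back to their minimum dose with a
warning.

## The phantom generator

`phantom_spec()` describes what the study conditions require, not
anatomy: a 10×10×14 mm ellipsoidal target at the centre of an
80×80×28-voxel grid at 1×1×3 mm (echoing the ~0.6×0.6×3 mm anisotropy
of clinical pelvic MR while staying small), a spherical bladder and a
straight rectal tube abutting the target with ~2 mm gaps, a curved
sigmoid tube at intermediate distance, and a distant small-bowel blob
chain. All organs exceed 2 cm³ so D2cm³ is well defined. The seed
jitters organ positions by up to ±2 mm in-plane, giving distinct but
structurally identical cases. Rasterization never overwrites an earlier
structure; trimming beyond 20% of a primitive, or a rasterized volume
more than 20% from the analytic target, aborts generation rather than
silently distorting the geometry.

`perturb_prediction()` corrupts one organ into a synthetic "prediction"
with three controls: the flipped-voxel budget (fraction of organ
volume), the placement band (`near`/`far`/`uniform` in distance to the
target), and the mode (`erode` boundary voxels out, `dilate` background
in, or `transfer` both). Erode-mode near and far errors of equal budget
produce *identical* vDSC by construction — the cleanest demonstration
that vDSC cannot see error placement.

What the phantoms do **not** emulate: MR intensities, applicator
geometry beyond a dwell line, deformable or overlapping anatomy, and
inter-observer contour styles. Passing tests therefore establish the
metric and loss machinery's correctness and its distance sensitivity —
not performance claims about real patients.

## The study driver

`run_study()` assembles the correlation analysis: per case and organ it
builds paired near- and far-band perturbations with a matched error
budget drawn from U(0.02, 0.08) (modest, so placement rather than
volume dominates dose error), evaluates all six metrics and the
absolute D2cm³ difference, pools records across cases, organs and
conditions (the same pooled design used when several models contribute
records), correlates each metric with $|\Delta D2cm^3|$ by Pearson's
$r$ with an ordinary least-squares line, and runs paired Wilcoxon
signed-rank tests between the near and far conditions for wDSC and vDSC
per organ — 8 comparisons, hence the Bonferroni threshold
$0.05/8 = 0.00625$. With erode-mode perturbations the vDSC near/far
test is degenerate (every paired difference is exactly zero); the
report flags it as such rather than inventing a p-value, and that
degeneracy *is* the finding — vDSC carries no placement information.

The Wilcoxon test is implemented with mid-ranks for ties, the exact
$2^n$ sign-enumeration null for up to 12 non-zero differences, and a
tie-corrected normal approximation with continuity correction beyond —
the exact path is needed because tied metric values are routine at
these sample sizes.

At the default 50 cases × 4 organs × 2 conditions (400 records, a few
minutes on one CPU), the study reproduces the qualitative finding the
machinery exists to demonstrate: wDSC correlates negatively and most
strongly with D2cm³ error, while vDSC's correlation is weak. The
magnitudes depend on the generator's error model and are not comparable
to clinical cohorts.

## Known limitations

* Exclusive labels: overlapping clinical contours must be split into
  separate one-label volumes before use.
* No resampling: ground truth and prediction must share a grid exactly;
  resampling changes metric values and is out of scope.
* The dose surrogate supports relative, not absolute, dosimetric
  statements.
* APL connectivity and in-plane scaling follow documented package
  choices where the formula itself is silent.
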