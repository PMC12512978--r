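---
title: "Atlas comparison and motor-sensory thalamic segmentation: methods"
author: "thalaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas comparison and motor-sensory thalamic segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalaseg)
```

# The problem

Ventral intermediate (VIM) thalamic deep brain stimulation treats essential
tremor, but clinical MRI cannot resolve thalamic subnuclei, so targeting
leans on atlases — and published thalamic atlases disagree substantially on
where the motor and sensory subnuclei sit. `thalaseg` implements a
reusable pipeline for quantifying that disagreement and its clinical
consequences:

1. **Inter-atlas comparison** — co-register the left thalami of a set of
   atlases pairwise with ICP and tabulate Dice coefficients for the whole
   thalamus and for the motor and sensory unions.
2. **Patient segmentation** — register each atlas to each patient thalamus
   and segment the patient with two techniques: prescriptive atlas-based
   segmentation (ABS) and a seeded k-means over spatial plus
   diffusion-tensor features (DTIBS).
3. **Clinical correspondence** — score each stimulation volume (VTA)
   against the segmented motor and sensory regions, and compare
   therapeutic against side-effect (sustained paresthesia) outcomes with
   paired Wilcoxon signed-rank tests under Bonferroni-Holm adjustment.

Because the clinical inputs (patient thalamus tracings, tensor fields, VTA
models) are not freely redistributable, the package ships a synthetic-data
generator that emulates their statistical structure with known ground
truth, so the entire analysis runs — and is tested — end to end without
external data.

# Registration

Thalami are registered as surface point clouds: boundary voxel centres
(true voxels with at least one false 6-neighbour), since the interiors of
solid blobs add no shape information. `icpRegister()` alternates exact
nearest-neighbour correspondence with a closed-form least-squares
(Umeyama/Procrustes) rigid update, stopping when the RMS residual changes
by less than `tol` (default 1e-6 mm) or after `maxIter` (default 100)
iterations.

Three choices here were genuinely open and deserve a record:

* **Initialization.** ICP is a local method. We initialize by aligning
  centroids and the principal axes of the point covariance. The axis signs
  are ambiguous, and moment-based sign disambiguation is unstable for
  near-centro-symmetric shapes like thalami; we therefore run ICP from all
  four proper sign combinations and keep the branch with the lowest
  *symmetric* (bidirectional) surface RMS. The one-way residual is too
  forgiving of pose flips — a flipped egg still finds a nearby surface
  point for every moving point — while the symmetric residual penalizes
  fixed-surface regions left uncovered.
* **Scale.** In similarity mode the isotropic scale is estimated once, in
  closed form, as the ratio of the clouds' RMS radii about their
  centroids, and rigid ICP runs on the pre-scaled cloud. Refitting scale
  inside the loop (full similarity Umeyama per iteration) can collapse the
  scale when the two surfaces are sampled at different resolutions: the
  moving cloud shrinks into a patch of the fixed one and the one-way cost
  still falls. The RMS-radius estimator is exact on noiseless data and
  immune to that degeneracy.
* **Mode per analysis.** Atlas-to-atlas comparisons use rigid ICP (the
  atlases live in a common template space); atlas-to-patient registration
  uses similarity mode, because atlas and patient thalami genuinely differ
  in size. In the pipeline the sparse patient surface is registered onto
  the dense atlas surface and the transform inverted, which halves the
  correspondence quantization error relative to the opposite direction.

Both clouds are capped at `maxPoints` (default 2000) by deterministic
stride subsampling, keeping the exact O(NM) correspondence affordable.

# Atlas-based segmentation

`absSegment()` applies the registered atlas prescriptively: a patient
voxel inside a subnucleus takes its label; a patient voxel outside every
subnucleus takes the label of the nearest labelled voxel in world
millimetres. Distance ties break toward the lowest label id, which makes
the operation deterministic and testable against a brute-force scan.

# DTI-based segmentation

`dtibsSegment()` is a seeded k-means over the patient's thalamic voxels.
The seeds are the subnucleus centroids of the registered atlas, so the
number of clusters k equals the atlas subnucleus count. The voxel-cluster
distance is

$$d_{jk} = \lVert x_j - \bar{x}_k \rVert_{W_k}
  + \alpha \, \lVert K(D_j) - K(\bar{D}_k) \rVert
  + (1-\alpha) \, \lVert U(D_j) - U(\bar{D}_k) \rVert_F$$

with the Mahalanobis spatial term
$\lVert v \rVert_{W_k} = \sqrt{v^\top W_k^{-1} v}$ over the cluster's
spatial covariance $W_k$, a tensor *shape* term over three rotational
invariants $K$, and a tensor *orientation* term over the principal
eigenvector dyadic $U = e_1 e_1^\top$. The weight $\alpha$ defaults to
0.5, balancing shape against orientation. Iteration recomputes
$\bar{x}_k$, $W_k$ and the cluster mean tensor $\bar{D}_k$ until every
centroid moves less than 0.1 mm (the convergence criterion) or `maxIter`
is reached.

The invariant set and the orientation representation are deliberate,
recorded choices rather than quotations: we take $K$ = (trace, fractional
anisotropy, tensor mode) — an orthogonal triple covering size, anisotropy
magnitude and anisotropy type (linear vs planar) — and the eigenvector
dyadic for orientation because it is invariant to the sign of $e_1$ and
Frobenius-comparable ($\lVert U_a - U_b \rVert_F = \sqrt{2}$ for
orthogonal principal directions). Other invariant sets exist; anyone
reproducing a specific prior implementation should check this definition
first.

Further numerical policy, all configurable:

* **Unit balancing.** The three shape features mix units (trace is in
  mm²/s, FA and mode are dimensionless), and the spatial term is already
  dimensionless. By default each shape feature is standardized by its
  median absolute deviation over the patient's thalamic voxels
  (`featureScaling = "mad"`); `"none"` reproduces a literal unscaled
  reading, and a numeric triple gives manual control. Note that a feature
  that is nearly constant across the thalamus (e.g. mode in a uniformly
  prolate phantom) has a noise-dominated MAD, so its standardized values
  are noise of order one — harmless in the presence of informative
  features, but worth knowing.
* **Covariance regularization.** $W_k$ is inverted as
  $W_k + \varepsilon I$ with $\varepsilon = 10^{-4}\,\mathrm{tr}(W_k)/3$
  (floor $10^{-6}$ mm²); clusters with fewer than 10 voxels fall back to
  the pooled within-cluster covariance. Without this, small clusters make
  the Mahalanobis term singular.
* **Initial statistics.** Seeds from `atlasSeedStatistics()` carry the
  registered subnucleus' spatial covariance and its mean tensor under the
  patient field — the natural iteration-0 state. Plain centroid matrices
  are also accepted (identity covariance, tensor of the nearest voxel),
  which reduces the first assignment to a seed Voronoi partition.
* **Ties and empty clusters.** Arg-min ties go to the lowest cluster
  index. A cluster that empties is frozen at its last nonempty statistics
  and reported; it is not reseeded.
* **Tensor averaging.** $\bar{D}_k$ is the arithmetic component mean by
  default; a log-Euclidean option exists for users who prefer
  swelling-free averaging.
* **Covariance volume cap.** Per-cluster Mahalanobis k-means has a
  runaway failure mode: a cluster whose covariance grows sees all its
  normalized distances shrink, swallows more voxels, and grows further.
  Updated covariances therefore keep their shape but have their
  determinant capped at 25 × the geometric-mean initial cluster
  determinant; the cap never engages in well-seeded runs.

A practical warning that mirrors the published experience with this class
of method: DTIBS quality depends strongly on seed quality. When the
registered atlas is misaligned (e.g. a few percent of scale error), the
seed subnuclei are impure, their mean tensors are mixtures that blur the
tensor terms, and the clustering can degrade sharply — up to near-total
collapse into a few clusters, which the pipeline logs via the emptied-
cluster report. ABS degrades gracefully under the same misregistration.
This asymmetry is a finding of the analysis, not an artifact to be
engineered away.

`seedSensitivity()` repeats the segmentation (default 100 runs) with every
seed centroid displaced independently and uniformly within a 2 mm ball
(sampled by rejection from the bounding cube) and reports both the
per-voxel modal-assignment agreement and the distribution of pairwise
adjusted Rand indices — two complementary readings of "stability", since
no single definition is canonical.

# Metrics

* `dice()` — $2|A \cap B| / (|A| + |B|)$ by voxel counts on a common
  grid. The inter-atlas protocol is pinned as: register the moving atlas
  surface to the fixed surface (rigid), resample the moving labels
  nearest-neighbour onto the *fixed* grid, count voxels there. Counting on
  the fixed grid after surface registration is one of several defensible
  conventions; mesh-volume variants would shift third-decimal values.
* `regionVolume()` — voxel count × voxel volume, always in the object's
  native grid (atlas 0.5 mm isotropic, patient 1 × 1 × 2 mm), so
  mixed-grid comparisons must resample explicitly rather than silently.
* `centroidDistance()` — Euclidean distance between the unweighted mean
  voxel-centre coordinates of the region and of the whole thalamus (no
  partial-volume weighting).
* `vtaOverlap()` — $|VTA \cap Region| / |VTA| \times 100$; deliberately
  asymmetric (normalized by the VTA only), so motor and sensory overlaps
  of one VTA against disjoint regions sum to at most 100.

# Statistics

`wilcoxonSignedRank()` implements the paired two-sided signed-rank test
with explicit conventions: zero differences dropped (Wilcoxon's
convention; Pratt's zero-ranking available), midranks for ties, the exact
null distribution of the positive-rank sum enumerated by dynamic
programming for effective n ≤ 25 (valid under ties, where the classical
tables are not), and a normal approximation with continuity and tie
correction beyond. The reported statistic is W = min(W⁺, W⁻). The exact
path is cross-checked in the tests against full 2ⁿ enumeration and against
`stats::wilcox.test` on tie-free data.

`holmAdjust()` delegates to `stats::p.adjust(method = "holm")`. Families
follow the analysis structure: within each analysis (each figure-analogue)
the per-atlas tests form one family, so six atlases give m = 6. Family
membership is recorded in every stats row. Significance is a Holm-adjusted
p below 0.05.

`buildParesthesiaPairs()` implements the duplication rule for the
side-effect analysis: each paresthesia VTA is paired with its patient's
single therapeutic VTA-sensory overlap, so a patient with three
paresthesia VTAs contributes the therapeutic value three times. The
pairing errors loudly if a paresthesia record has no therapeutic partner.

# The synthetic generator

The generator defines the study conditions for every test in the package,
so its design is spelled out here.

**Geometry.** Each hemisphere is an "egg": an ellipsoid (default radii
7.7 × 11.9 × 6.3 mm, ≈ 2450 mm³) whose cross-section widens linearly
toward the anterior pole and whose cross-section centre follows a
quadratic dorsal bend. The taper breaks anterior-posterior flip symmetry
and the bend breaks the remaining 180° rotation, so the shape has *no*
nontrivial proper self-symmetry — a plain ellipsoid would make ICP
transform recovery ill-posed. The size is below a real thalamus
(≈ 6–8 cm³) but large enough that a patient thalamus on the clinical
1 × 1 × 2 mm DTI grid carries ≈ 1200 voxels, a regime comparable to
clinical data for cluster-stability purposes; runtimes scale with it. Each
atlas additionally jitters the egg parameters deterministically from its
seed (radii ± 8 %, taper/bend/centre perturbations), because published
atlases disagree on the outer thalamic boundary as well as on the
parcellation — without this, whole-thalamus Dice between synthetic atlases
would be trivially ≈ 1.

**Parcellation.** Each hemisphere is split into k contiguous Voronoi cells
from Poisson-disk-like generator points sampled inside the egg. Motor
cells are the most anterior-lateral generators, sensory cells the most
posterior of the rest — the topology shared by published motor/sensory
parcellations. The right hemisphere mirrors the left.

**Patients.** A patient thalamus is an atlas hemisphere mapped through a
random similarity transform (rotation 5–20°, translation ± 5 mm, scale
0.9–1.1), its surface perturbed and re-voxelized at 1 × 1 × 2 mm. The
perturbation adds a smooth random field to the signed distance of the
voxelized support: Gaussian kernels anchored on the surface with iid
normal coefficients, self-normalized so the pointwise standard deviation
is exactly `surfaceNoiseSd` (default 0.4 mm) wherever kernel coverage
exists. The zero level set sits on the in/out voxel interface (inside
voxels measure distance to outside centres and vice versa), so zero noise
reproduces the support exactly. Truth labels are the nearest-neighbour
resampled atlas labels, extended to noise-added voxels by nearest-label
assignment; they always partition the mask.

**Tensors.** Every subnucleus gets an axially symmetric tensor with a
distinct principal direction (spread over the upper unit hemisphere, so
dyadics are distinct) and a distinct (mean diffusivity, FA) pair — MD
0.60–0.85 × 10⁻³ mm²/s and FA 0.30–0.75 across subnuclei, physiological
ranges with deliberately strong contrast. Gaussian component noise
(sd 4 × 10⁻⁵ mm²/s, ≈ 5 % of MD) is added and eigenvalues floored at
10⁻⁶, so every stored tensor is symmetric positive definite. Two knobs
(the MD/FA ranges and the direction spread) control recovery difficulty.

**VTAs.** Ellipsoidal masks of nominal radius 2.5 mm. The therapeutic VTA
centres in the true motor region (jittered until the centre voxel is
motor); paresthesia VTAs centre 0.7 of the way from the motor to the
sensory centroid plus 1 mm jitter. About 12/22 of patients have
paresthesia VTAs, 2–4 each, mirroring the clinical cohort mix the analysis
emulates. The physics of tissue activation is out of scope: VTAs are
consumed as masks, and the 0.2 V/mm field-threshold definition is
provenance only.

**What passing tests do and do not show.** The generator produces exactly
the structure the methods assume: well-separated per-region tensors,
transforms inside the similarity family, and VTAs placed to contain the
expected clinical pattern. Recovery and pipeline tests therefore validate
the *implementation* — that each algorithm does what it claims under its
own assumptions — not the clinical claims. Real thalami have continuous
boundaries between nuclei, registration error from the imaging pipeline,
non-similarity shape variation, and far noisier tensors; numbers obtained
on the phantoms do not transfer.

# Problem sizes

The test suite and the acceptance script run, as the package's own choice
of scale: six synthetic atlases with 10–46 subnuclei per hemisphere on
0.5 mm grids; cohorts of up to 20 patients (≈ 1200 thalamic voxels each);
100 ICP transform recoveries on 300-point clouds; 100-run seed-sensitivity
analyses; and full 6 × 6 inter-atlas Dice tables. DTIBS recovery is
scored on truth-transform seeding (isolating clustering quality from
registration error, in parallel with the ABS ground-truth identity check);
the pipeline runs use fitted ICP registrations throughout.

# Known limitations

* The exact invariant set and term weighting of the original DTIBS
  distance are underdetermined; ours is one defensible instantiation,
  exposed as configuration (`alpha`, `featureScaling`, `tensorMean`).
* Reproducing the published inter-atlas Dice tables requires the six
  Lead-DBS atlas distributions converted to NIfTI plus a subnucleus
  metadata JSON (label → name/class/hemisphere). `interAtlasDice()`
  accepts such bundles directly; the packaged metadata fixture records the
  per-atlas subnucleus counts. The conversion itself (MAT-file reading) is
  intentionally not automated here.
* No deformable registration, no tractography/spectral/NN segmentation,
  no tensor estimation from raw diffusion-weighted images, no electric
  field modelling.
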