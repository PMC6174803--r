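---
title: "Liver CT segmentation with registration-based positioning and joint coarse-to-fine refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liver CT segmentation with registration-based positioning and joint coarse-to-fine refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ropseg implements a liver (and liver-tumor) delineation pipeline for
abdominal CT in three stages: registration-based organ positioning (ROP),
a joint fuzzy-c-means / extreme-learning-machine coarse segmentation with
accuracy-weighted fusion, and active-contour boundary refinement. This
vignette is the package's account of the underlying models, the parameters
that matter, the synthetic data that exercises them, and the numerical and
design choices a maintainer should know about.

## The positioning model

Liver location and size vary between patients, so a fixed bounding box
either clips the organ or admits large amounts of irrelevant anatomy. ROP
instead selects one *standard* subject from a labelled cohort — the subject
whose liver volume is closest to the cohort mean, with volume measured as
the convex hull of the labelled voxel centres (`convex_hull_volume()`;
hull of centres, so a solid a×b×c box scores (a−1)(b−1)(c−1) voxel units)
— and registers that subject's slices onto each unseen slice.

The direction of registration is the point: the template is always the
*float* (moving) image and the unseen slice the *reference* (fixed) frame.
The recovered affine maps template coordinates into the unseen slice, which
is exactly the direction needed to push the template's liver-label extent
forward into a bounding box (`propagate_bbox()`: transformed label
coordinates, min/max, rounded outward — floor on minima, ceiling on maxima
— then clipped and converted to half-open indexing). Registering in the
conventional direction would require inverting the transform to carry the
label; here no inverse is ever formed, and the package exposes no
inverse-registration path.

Registration itself (`register_slice()`) is a two-stage intensity-based 2D
affine fit (translation, rotation, per-axis log-scale, shear) by
Nelder–Mead: a coarse stage maximizing normalized cross-correlation on
2×-downsampled images with a large step, then a fine stage minimizing
mean-squared difference at full resolution with a step one tenth the size
and four times the iterations (200 coarse / 800 fine). The fine stage
starts from the coarse optimum, so its objective can only improve on it.
The fine metric is evaluated on a stride-2 grid of the full-resolution
images; this quarters the cost per objective evaluation without changing
the optimum measurably at the phantom's resolution.

Template and subject are brought to a common z spacing (1.60 mm by default,
the common slice thickness of abdominal protocols) by linear interpolation
(`interpolate_z()`, labels re-binarized at 0.5), and slices correspond by
proportional index. When a subject slice maps just beyond the template's
liver range, the nearest liver-bearing template slice within `z_extend`
(default 4) slices is borrowed; the per-slice affine still adapts the box.
Consecutive slices warm-start from the previous transform, and the coarse
stage re-runs whenever the warm-started fine metric degrades past 0.05.
Positioning runs on preprocessed (liver-windowed) slices by default, which
focuses the similarity metrics on the tissue that matters; the raw images
can be used instead (`enhanced = FALSE`).

## Preprocessing

Liver parenchyma concentrates in a narrow gray band, 130–150 by default.
`preprocess_slice()` zeroes everything outside the window and maps the
window linearly onto [1, out_max]: the low edge goes to 1, not 0, so a
preserved pixel can never collide with the zeroed background. A 5×5 median
filter (exact, edge-replicated) removes impulse noise. When a statistics
patch is supplied, the window is estimated as the histogram mode ± the
half-width at half-maximum (bounded below by 5 gray units); without a
patch the standard window is used. The patch is an explicit argument
rather than a random crop: randomness in preprocessing would make runs
irreproducible.

## The coarse stage

**Clustering.** `fcm_cluster()` is the standard alternating fuzzy c-means
(fuzzifier m = 2, tolerance 1e−5, seeded random centre initialization)
with c = 4, since a liver box contains liver, fat, background and other
organs. Membership rows sum to 1 to 1e−9 and the objective is
non-increasing — both asserted in tests. `fcm_liver_mask()` hard-assigns
pixels, takes as foreground *all* clusters whose centres lie in the upper
stretched range (≥ 0.25·out_max), keeps the largest 8-connected component
(ties to the component containing the lexicographically smallest pixel),
closes with a disc of radius 3 and fills holes. The foreground rule is
deliberately a set, not the single cluster nearest the window midpoint:
with four clusters on a windowed slice the broad liver mode is routinely
split in two or three, and any single cluster recalls only a band of the
organ. Merging the in-window clusters restores recall, while the
largest-component step still drops a neighbouring in-window organ unless it
touches the liver — which is precisely the oversegmentation failure mode
this stage is known for, and the reason for the fusion below.

**Pixel classification.** `extract_features()` computes a fixed
126-dimensional descriptor per pixel from 16 classic families (gray value;
Gaussian derivatives of both orders at σ ∈ {1,2,4}; local standard
deviation; bottom-hat; phase congruency; Canny; Harris; uniform
rotation-invariant LBP(8,1) histograms over 9×9 windows; Gabor magnitudes
at 4 orientations × 3 frequencies; Hessian eigenvalues; neighbourhood
mean/variance; local entropy; co-occurrence contrast/correlation/energy/
homogeneity at 4 offsets; 25 Laws kernels; sum-and-difference histogram
statistics). The family list is fixed; the per-family dimensionalities are
this package's declared convention (they sum to 126) and are frozen in
`feature_spec()` — any consistent partition preserves the method, and
fixing one makes it reproducible. All features are deterministic and
translation-covariant in the image interior except phase congruency
(computed by FFT, so border-influenced) and the Canny threshold (a global
quantile).

`elm_train()` solves the single-hidden-layer network in closed form:
random input weights and biases uniform on [−1,1], hidden outputs
H_ij = sin(x_i·w_j + b_j), output weights β = H⁺T via SVD with relative
singular-value truncation at 1e−10 and no ridge term. Inputs are z-scored
and additionally scaled by 1/√d: the random projection then has unit-order
variance for any input dimension, keeping the sine in its informative
range (without this, 126-dimensional inputs wrap the sine through several
periods and training accuracy collapses). With at least as many hidden
units as distinct samples the network interpolates the training data
exactly; the default hidden width is 630. Ties at the 0.5 decision
threshold go to the foreground.

**Fusion.** Clustering tends to oversegment and the classifier to
undersegment, so the coarse mask is their weighted combination. Per
training slice the stage accuracies A_F, A_E give slice weights
A_F/(A_F+A_E) and A_E/(A_F+A_E); the final pair is the mean over the
top-K slices ranked by max(A_F, A_E), K = min(100, n). `fuse()` combines
soft score maps where available (liver-cluster membership, clamped ELM
scores) — soft fusion degrades gracefully to binary fusion and dominated
it in development — then applies the shared post-processing: 5×5 median
and threshold at 0.5 with ties to 1. Degenerate weights (1,0)/(0,1)
reproduce the single stages exactly up to that shared post-processing.

## The refinement stage

`refine()` traces the coarse boundary (`mask_to_contour()`: boundary
pixels of the largest component, resampled to 200 points by arc length,
pushed half a pixel along outward normals so the polyline marks the region
edge rather than the boundary pixel centres), then evolves a closed
parametric snake. Internal energy is the usual continuity + curvature pair
(α = 0.1, β = 0.5) assembled into a pentadiagonal stiffness matrix; the
update is the semi-implicit x ← (I + γA)⁻¹(x + γf(x)) with γ = 0.5. The
external force f is the gradient of the Gaussian-smoothed (σ = 2) edge
magnitude, diffused with a σ = 1 Gaussian and normalized to unit vectors:
direction is what matters for advection, and the plain gradient decays so
fast that a contour a few pixels off stalls. Any step that would raise the
total energy is rejected and γ halved, so the accepted energy trace is
non-increasing by construction; evolution stops when the mean displacement
drops below 0.02 px (a tolerance of 0.1 px stops the contour while the
unit-magnitude force is still advecting it, which is why the default is
tighter) or after 500 iterations. The snake runs on the windowed/stretched
slice *before* median smoothing: the median erodes the windowed liver
support by about a pixel and would bias the contour inward. Rasterization
is even-odd scanline fill over pixel centres; the output keeps a single
filled component, and any failure returns the coarse mask flagged — the
snake is sensitive to its initial contour, so the coarse mask is the
fail-safe. Refinement is per-slice 2D; no balloon force is used, keeping
the coarse contour authoritative.

## The tumor stage

A second ELM is trained on the same 126-dimensional features, restricted
to pixels inside the liver: tumor = 1, other liver tissue = 0. Training
uses ground-truth liver masks; inference uses the predicted liver (the
standard cascade convention — documented, since the stages are then not
independent). Scores are median-filtered, thresholded at 0.5 and
intersected with the liver mask, so tumor ⊆ liver holds by construction.

## The synthetic phantoms

`generate_phantom()` builds what the pipeline assumes and nothing more: a
liver as a smoothly deformed ellipsoid (low-frequency cosine perturbation
of the radius, amplitude 0.05) with voxel gray values N(140, 4) — about
98.8 % of which fall in the 130–150 window before additive noise — darker
tumors N(112, 4) strictly inside it, a spleen-like confounder at
liver_mean + 5 (inside the window, so clustering sees overlapping gray
values), a soft-tissue body at 100 on an air background at 20, and
additive N(0, 2) noise. Each cohort subject receives an independent affine
(per-axis scale 0.92–1.08, in-plane rotation ±8°, translation ±4 % of the
extent). The default 3D grid is 64×128×128 at (4, 3, 3) mm — a
coarse-voxel stand-in for clinical resolution chosen so problem sizes stay
desk-scale — and the default liver semi-axes make the mean cohort liver
volume land near 1720 cm³, the average reported for abdominal CT cohorts.
The 2D fast mode (one 128×128 slice at (1.6, 0.78, 0.78) mm) carries the
unit and end-to-end tests.

What the phantoms do *not* model: CT physics (beam hardening, HU
calibration), respiratory motion, vessel trees, lesion heterogeneity, or
anatomically shaped organs. Passing on phantoms therefore demonstrates
that the pipeline's machinery — positioning, clustering, classification,
fusion, refinement, evaluation — is implemented correctly and recovers
known geometry under controlled intensity overlap and noise; it does not
certify clinical accuracy on patient data.

## Evaluation

`evaluate_all()` reports the six standard criteria: VOE (100×(1−Jaccard)),
signed RVD, ASD/RMSD/MSD over symmetric nearest-surface distances, and
Dice. Surface voxels are foreground voxels with a background
face-neighbour (6-connectivity in 3D, 4 in 2D; out-of-grid counts as
background — the connectivity convention is frozen here). Distances are
Euclidean between voxel centres after per-axis spacing scaling, computed
by chunked exact nearest-neighbour search and verified against a
brute-force all-pairs oracle to 1e−9 in the tests. Undefined cases (empty
masks) return NA with a per-metric flag rather than failing the report.

## Problem sizes and determinism

Test and acceptance runs use desk-scale problems chosen to exercise every
code path: 16³ random masks for the metric oracle, single-slice 128×128
phantoms for the stage and end-to-end tests (6 training / 2 held-out
subjects), a 6-subject 64×128×128 cohort for 3D positioning, and 5-fold
cross-validation over 10 subjects (the 10-fold/20-subject fold arithmetic
is validated on the plan directly). Every stochastic component — phantom
cohorts, FCM initialization, ELM weights, CV folds — draws from an
explicit seed through an RNG-state-preserving helper, so identical
configurations reproduce masks, models and reports bit-exactly; this is
itself under test.

## Known limitations

- The affine registration model cannot follow strongly non-affine
  inter-subject deformation; boxes stay correct (they are outward-rounded
  and padded) but tight-box ratios grow with shape variability.
- The snake's energy-descent guarantee is with respect to its sharp-edge
  energy while the advection uses the diffused normalized force; in
  pathological fields the contour may stop early rather than overshoot.
- Feature extraction cost (~2 s per 128×128 slice, dominated by the
  co-occurrence energy maps) makes full 3D classifier inference expensive;
  the package processes slices independently and does not regularize
  across z.
- Tumor inference inherits any liver-stage error: a missed liver region
  can never contain a detected tumor.
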