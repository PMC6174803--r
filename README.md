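# ropseg

Automatic liver and liver-tumor delineation in abdominal CT, built around
three ideas:

1. **Registration-based organ positioning (ROP).** A *standard* subject —
   the one whose convex-hull liver volume is closest to the cohort mean — is
   kept as a template. For every slice of an unseen volume, the template
   slice is registered **as the float image** onto the unseen slice (the
   reference), and the template's liver-label extent is pushed through the
   recovered affine to give a per-slice bounding box. Because the box is
   carried through the forward transform, no inverse registration is ever
   computed.
2. **Joint coarse segmentation.** Inside each box, two pixel-wise stages
   run on the preprocessed slice (liver gray window 130–150, contrast
   stretching, 5×5 median): fuzzy c-means clustering with c = 4, and an
   extreme learning machine (ELM) over a 126-dimensional per-pixel texture
   descriptor — a single hidden layer of 630 sine units with random input
   weights and closed-form output weights β = H⁺T (Moore–Penrose). The two
   masks are fused with accuracy-derived weights
   w_F = A_F/(A_F + A_E), w_E = A_E/(A_F + A_E)
   measured on training slices, then median-filtered and thresholded.
3. **Coarse-to-fine refinement.** The coarse boundary initializes a
   parametric active contour (snake) that minimizes continuity + curvature
   internal energy against an image-gradient external energy, recovering
   boundary detail that pixel-wise classifiers miss. A second ELM then
   classifies pixels inside the segmented liver as tumor / non-tumor.

The package is exercised end-to-end on synthetic abdominal phantoms
(`generate_phantom()` / `generate_cohort()`): a deformed-ellipsoid liver
with gray values concentrated in the 130–150 window, darker tumors strictly
inside it, a confounder organ overlapping the liver window, per-subject
affine variation, and a default 3D geometry whose mean liver volume sits
near 1720 cm³. Evaluation uses the six standard criteria: VOE, RVD, ASD,
RMSD, MSD and Dice (surface distances in mm, spacing-aware).

## Worked example

```r
library(ropseg)

# a small 2D-mode phantom cohort: 8 subjects, 2 tumors each
cohort <- generate_cohort(8, phantom_params(shape = c(1, 128, 128),
                                            spacing = c(1.6, 0.78, 0.78),
                                            n_tumors = 2, seed = 0), seed = 5)

bundle <- train_liver(cohort[1:6])     # template + ELM + fusion weights
print(bundle)
#> liver_bundle: template subject 1, ELM L=630, weights (0.499, 0.501)

tmodel <- train_tumor(cohort[1:6])
sub <- cohort[[8]]
fine <- segment_liver(sub$volume, bundle)
tumor <- segment_tumor(sub$volume, fine, tmodel)

print(evaluate_all(sub$liver$voxels, fine$voxels, sub$volume$spacing))
#> VOE 0.88%  RVD -0.71%  ASD 0.104 mm  RMSD 0.285 mm  MSD 0.780 mm  DICE 99.56%
dice(sub$tumor$voxels, tumor$voxels)
#> [1] 97.14286
```

The liver Dice near 99.6 % says the held-out phantom liver is recovered
almost exactly; ASD ≈ 0.06 mm means the predicted surface sits a small
fraction of a pixel from the true one on average. Tumor Dice ≈ 97 % with
the tumor mask contained in the predicted liver by construction.

A command-line front end mirrors the library
(`inst/cli/ropseg phantom|position|train|segment|tumor|evaluate|cv`);
volumes and masks travel as NIfTI, boxes and reports as JSON.

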