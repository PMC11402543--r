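---
title: "Validating multi-observer prostate GTVs against histopathology: methods"
author: "gtvhisto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multi-observer prostate GTVs against histopathology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtvhisto)
```

## The problem

Focal dose escalation in prostate radiotherapy requires knowing how well an
imaging-defined gross tumour volume (GTV) captures the true intraprostatic
lesion. The only reliable ground truth is whole-mount histopathology after
prostatectomy: digitally delineated, Gleason-graded tumour foci on serial
sections, co-registered to the in-vivo images. `gtvhisto` implements the
analysis machinery for such a validation study: several observers delineate
the GTV on several image types (axial T2-weighted MRI, diffusion-weighted
MRI, dynamic contrast-enhanced MRI, and PSMA-PET), the delineations are
fused into consensus GTVs, and each GTV — with and without isotropic CTV
margins — is scored voxel-wise against the histopathology lesion.

All masks live on regular, axis-aligned 3D voxel grids with the voxel-centre
convention: voxel index $(k, j, i)$ (0-based, slice/row/column order) sits at
physical position $\mathrm{origin} + (k, j, i) \odot \mathrm{spacing}$.
Because the image types have different slice thicknesses, every mask is
resampled (nearest-neighbour, ties toward the lower index) onto the
histopathology reference grid before analysis; all metrics are computed
there. Orientation matrices beyond axis-aligned grids are rejected rather
than silently reinterpreted — the analysis is intra-patient on co-registered
volumes, where non-trivial direction cosines would indicate an upstream
processing error.

## Consensus GTVs: STAPLE and union-then-STAPLE

Binary STAPLE (Simultaneous Truth And Performance Level Estimation)
estimates, by expectation-maximization, the posterior probability
$W_i = P(T_i = 1 \mid d)$ that voxel $i$ belongs to the unknown true
segmentation, jointly with each observer $j$'s sensitivity $p_j$ and
specificity $q_j$, from the binary decisions $d_{ij}$:

$$a_i = \gamma \prod_j p_j^{d_{ij}} (1-p_j)^{1-d_{ij}}, \qquad
  b_i = (1-\gamma) \prod_j (1-q_j)^{d_{ij}} q_j^{1-d_{ij}}, \qquad
  W_i = \frac{a_i}{a_i + b_i},$$

$$p_j = \frac{\sum_i W_i d_{ij}}{\sum_i W_i}, \qquad
  q_j = \frac{\sum_i (1-W_i)(1-d_{ij})}{\sum_i (1-W_i)}.$$

Numerical and initialization choices, which the STAPLE literature leaves
open, are fixed as follows:

* **Prior $\gamma$**: the mean foreground fraction over observers, held
  fixed across iterations (`prior_mode = "global_fraction"`). Re-estimating
  $\gamma$ each iteration is known to let the posterior drift towards
  trivial solutions; a fixed, data-driven global prior is the simplest
  reproducible choice. A `fixed` mode accepts a user prior.
* **Initialization**: $W$ starts at the voxelwise mean of the observer
  decisions and the first step is the M-step — deterministic and
  independent of observer count.
* **Clamping**: $p_j, q_j \in [10^{-6}, 1-10^{-6}]$ after each M-step, so
  unanimous regions cannot produce $0 \cdot \log 0$ degeneracies.
* **Convergence**: iteration stops when the mean absolute change of $W$
  falls below `tolerance` ($10^{-7}$ by default, at most 200 iterations).

The posterior is thresholded at $\tau = 0.95$ (inclusive, so a unanimous
consensus survives even $\tau = 1$) and cropped to the histopathology
support, excluding extraprostatic voxels from every comparison.

Two fusion schemes produce the GTV variants:

* **Single image type** (`fuse_single_modality`): STAPLE over the four
  observers' delineations of that type — GTVs T2w, DWI, DCE, PSMA-PET.
* **Multiple image types** (`fuse_multi_modality`): first each observer's
  delineations of the requested types are merged into a per-observer
  *union*, then STAPLE fuses the four unions — GTV bpMRI (T2w+DWI),
  mpMRI (+DCE), PSMA-PET/mpMRI (all four). The same $\tau = 0.95$ is used
  for single- and multi-modality fusion alike — one uniform threshold is
  the only consistent choice. Requesting a single type through this path
  reduces exactly to the single-modality scheme.

Interobserver variability is quantified by *individual* GTVs: each
observer's own delineation per image type, and their per-observer unions
for the multi-type combinations (no STAPLE involved).

## The histopathology reference

Histopathology arrives as per-slice delineations with Gleason patterns.
Delineations that overlap in-plane (at least one shared voxel — no area
threshold) on *consecutive* slices belong to one lesion; a one-slice gap
splits lesions, and same-slice delineations are never merged directly,
though they may be bridged through neighbouring slices. Lesion ids are
assigned in a canonical order derived from the sorted voxel sets, so the
labeling is independent of input ordering. The validation target is the
largest lesion by Gleason-4/5 volume, restricted to its pattern-4/5 voxels —
the package's operational stand-in for the clinically identified
dominant intraprostatic lesion (a modelling assumption, since clinical
dominant-lesion calls use more than volume).

## Overlap metrics and CTV margins

For a GTV $A$ and lesion $L$ on the reference grid:
$\mathrm{DSC} = 2|A \cap L| / (|A| + |L|)$ and lesion coverage
(voxel-wise sensitivity) $= |A \cap L| / |L|$. Comparing two empty masks is
an error, not a convention value: the pipeline cannot produce that case
legitimately, and a silent 1.0 or 0.0 would mask upstream bugs.

CTV margins expand the GTV isotropically in physical millimetres: the
expanded mask contains every voxel whose centre lies within `radius_mm` of
some foreground voxel centre. This is implemented as dilation with the
exact set of integer voxel offsets of physical length at most the radius,
which is precise on anisotropic grids — with 5 mm slices, a 3 mm margin
never leaves the slice. The standard margins are 0, 1, 2 and 3 mm; expansion
precedes cropping to the support, which precedes the metrics.

## The registration-uncertainty experiment

The histology-to-in-vivo registration has a known residual in-plane error
of about 1.7 mm. To bound its impact, each patient's GTV is rigidly
translated in-plane to maximize a penalized overlap objective

$$J(t) = \mathrm{DSC}(\mathrm{shift}(A, t), L) - \lambda\, \mathrm{pen}(\|t\|_2),$$

and the penalty weight $\lambda$ is calibrated so that the *population mean*
of the per-patient optimal translation distances equals the known 1.7 mm
error. The calibration volume is the all-MRI, all-observer union-then-STAPLE
GTV (`calibration_gtv`).

Three design points deserve comment:

* **Continuous overlap objective.** Under nearest-neighbour shifting the
  voxel Dice is piecewise constant in $t$, so any sub-voxel search
  resolution is illusory. `gtvhisto` instead treats voxels as physical
  boxes: the overlap volume of the *continuously* translated GTV with the
  lesion is then exactly the bilinear interpolation, in the fractional
  voxel displacement, of the integer-displacement correlation table. The
  objective becomes continuous piecewise-bilinear, agrees with the voxel
  Dice at voxel-aligned translations, and is evaluated exhaustively on a
  fixed 0.1 mm lattice over the 10 mm search disk (vectorized; ties broken
  towards smaller $\|t\|$, then lexicographically). The fixed lattice makes
  the per-patient optimum exact for the stated resolution and the mean
  distance provably non-increasing in $\lambda$.
* **Quadratic penalty.** Only *that* the translation distance is
  penalized is part of the experiment's definition; the functional form is
  a design choice of this package. The linear form $\lambda \|t\|$ interacts badly with
  a piecewise-linear objective: every optimum locks onto a surface
  breakpoint, per-patient distances jump discretely with $\lambda$, and the
  15-patient mean becomes a step function with $\sim$0.05–0.1 mm steps that
  bisection cannot steer to a 0.01 mm tolerance. With the quadratic form
  $\lambda \|t\|^2$ (the default) the within-basin optimum varies
  continuously with $\lambda$, the population mean is continuous up to the
  search resolution ($\sim$0.007 mm steps for 15 patients), and bisection
  converges. `penalty = "linear"` remains available for comparison.
* **Calibration by bisection.** The mean distance at $\lambda = 0$ is the
  uncorrected misregistration; if it is already below the target the
  boundary solution $\lambda^* = 0$ is returned with a warning. Otherwise
  the bracket is grown geometrically and bisected until the mean is within
  `tolerance_mm` (default 0.01 mm) of the target.

Translations are in-plane only, because the stated registration error is
in-plane. After calibration, `apply_calibrated_shift` re-evaluates the
STAPLE GTVs under each patient's optimal translation; since the zero
translation is always a candidate, the per-patient DSC can only improve,
matching the direction of the effect reported in validation studies of this
kind.

## The synthetic cohort

No patient data accompany this package; `generate_cohort` produces
desk-scale patients with the statistical structure the analysis assumes.
Defaults mirror the conditions of the emulated validation setting: 15 patients, four observers, four
image types, a 24 × 96 × 96 reference grid at (2.5, 1, 1) mm.

* **Gland (histopathology support)**: an ellipsoid of ~43 ml (semi-axes
  18 × 24 × 24 mm, ±10% jitter) — a typical prostatectomy specimen.
* **Lesion**: the superlevel set of a 1–3-component Gaussian blob field,
  thresholded inside the gland to hit a target volume drawn log-uniformly
  from 0.22–11.22 ml — the emulated cohort's Gleason-4/5 volume range, whose heavy
  right tail the log-uniform emulates without asserting the unknown true
  distribution. Only the largest z-connected component is kept, so the
  truth is a single lesion by the pipeline's own merging rule.
* **Gleason structure**: a connected sub-region of 85% of the lesion (grown
  from the field maximum) is labelled pattern 4 or 5; the remainder is
  pattern 3. Per-slice delineations are emitted and run through the real
  `merge_lesions_z`/`target_lesion_mask` path, so the reference target is
  produced by the same code a real study would use.
* **Observers**: each (observer, image type) mask is drawn from the STAPLE
  generative model — keep a truth voxel with probability $p$, add a
  background voxel with probability $1-q$ — with $p$ drawn per observer
  from per-modality ranges (T2w and DWI 0.75–0.90, DCE 0.60–0.80, PSMA-PET
  0.70–0.90; DCE is the weakest modality in practice) and $q$ from
  0.95–0.99. False positives are confined to a 5 mm shell around the
  lesion: a uniform $1-q$ over the whole gland would create implausible
  speckle and make $q$ uninformative.
* **Boundary noise**: modelled as a per-(observer, image type)
  over/under-segmentation — the truth is dilated or eroded by
  $b \sim N(0, 0.5\,\mathrm{mm})$, quantized to 0.5 mm — capturing
  systematic contouring style rather than high-frequency boundary wiggle,
  which a sensitivity/specificity model cannot represent anyway.
* **Misregistration**: each image type receives an in-plane translation
  $\delta \sim N(0, \sigma^2 I_2)$; the default
  $\sigma = 1.7/\sqrt{\pi/2} \approx 1.36$ mm makes the expected
  displacement norm equal the 1.7 mm residual registration error being
  modelled. The
  calibration experiment uses $\sigma = 4$ mm so the uncorrected optimal
  shifts clearly exceed the 1.7 mm target being calibrated to.
* **Randomness**: per-patient and per-(observer, image type) streams are
  derived from the master seed by counter-based hashing, so any patient can
  be regenerated alone, bit-identically.

The `noiseless = TRUE` configuration switches off every discrepancy source
($p = q = 1$, no boundary noise, no misregistration, Gleason fraction 1);
every fused GTV then equals the truth lesion exactly and all metrics are
1.0 at margin 0 — the pipeline's strongest end-to-end self-check.

What the generator does *not* emulate: image intensities (delineations are
sampled directly, never re-derived from synthetic images), observer bias
models beyond sensitivity/specificity/boundary offset, deformable
registration error, and multi-focal disease beyond what the blob field
produces. Passing tests therefore demonstrate the correctness of the
*analysis machinery* under the assumed statistical structure, not the
clinical performance figures of any real cohort — clinical overlap figures depend on real patient data that no simulation
can stand in for.

## Reporting conventions

Cohort summaries follow the standard reporting layout of such studies: for STAPLE GTVs the
median (min, max) over patients; for individual GTVs each observer's median
over patients is computed first, then the mean, maximum and minimum of the
four observer medians (so the two row families are not directly
comparable). Medians use the standard midpoint convention for even counts —
a 15-patient cohort never exercises this, but the package must behave
sensibly for any cohort size. Duplicate records are an error rather than
silently averaged.

## Problem sizes and runtime

The test-suite and acceptance workloads were sized for a single CPU:
the full default cohort (15 patients, 24 × 96 × 96 grid) generates in
~12 s; one STAPLE fusion of four observer volumes converges in 10–30
iterations (~0.2 s); the complete calibration experiment — cohort,
calibration GTVs, correlation tables, bisection — runs in ~40 s. The
straight-loop STAPLE reference used by the oracle tests is intentionally
unoptimized and dominates the unit-test runtime.

## Known limitations

* Only axis-aligned geometry; no DICOM/RT-STRUCT input; no deformable or
  rotational registration.
* The dominant-lesion rule (largest Gleason-4/5 volume) may differ from a
  clinical dominant-lesion call in multi-focal cases.
* The multi-modality STAPLE threshold (0.95) is a package convention
  (reusing the single-modality threshold), not an externally fixed value.
* Exact numerical agreement with any particular clinical software stack
  (whose prior, convergence and penalty internals are generally
  unpublished) is not claimed; the package claims internal consistency and
  correctness against independent oracles instead.
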