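# gtvhisto

Histopathology validation of multi-observer prostate gross tumour volumes
(GTVs), in R.

When several radiation oncologists delineate an intraprostatic tumour on
several image types — axial T2-weighted MRI (T2w), diffusion-weighted MRI
(DWI), dynamic contrast-enhanced MRI (DCE) and PSMA-PET — how well do the
resulting target volumes capture the true lesion seen on whole-mount
prostatectomy histopathology? `gtvhisto` implements the full analysis
pipeline for that question, for imaging scientists and radiotherapy
physicists who have (or simulate) co-registered binary delineation masks:

* **Consensus GTVs** by binary STAPLE expectation–maximization: per voxel
  $i$ and observer decisions $d_{ij}$, the posterior truth probability
  $W_i = a_i/(a_i+b_i)$ with
  $a_i = \gamma \prod_j p_j^{d_{ij}}(1-p_j)^{1-d_{ij}}$,
  $b_i = (1-\gamma) \prod_j (1-q_j)^{d_{ij}} q_j^{1-d_{ij}}$, and M-steps
  re-estimating each observer's sensitivity $p_j$ and specificity $q_j$;
  the posterior is thresholded at 0.95. Multi-modality GTVs (bpMRI, mpMRI,
  PSMA-PET/mpMRI) use the two-step *union-then-STAPLE* scheme: per-observer
  unions across image types first, STAPLE across observers second.
* **Histopathology reference**: per-slice Gleason-graded delineations are
  merged into 3D lesions (overlap on consecutive slices = same lesion) and
  the largest Gleason-4/5 region becomes the validation target.
* **Overlap metrics** against the lesion, on the histopathology grid:
  Dice similarity coefficient $\mathrm{DSC}=2|A\cap L|/(|A|+|L|)$ and
  lesion coverage (voxel-wise sensitivity) $|A\cap L|/|L|$, with isotropic
  CTV margins of 0–3 mm applied by exact physical-distance dilation on
  anisotropic grids.
* **Registration-uncertainty experiment**: per-patient penalized in-plane
  translation registration maximizing
  $J(t)=\mathrm{DSC}(\mathrm{shift}(A,t),L)-\lambda\,\|t\|^2$, with the
  penalty weight calibrated by bisection so the population-mean optimal
  translation distance equals the known 1.7 mm residual registration error.
* **Synthetic cohorts**: a generator producing 15-patient cohorts with the
  statistical structure of such validation studies (lesion volumes 0.22–11.22 ml, four
  observers × four image types with per-modality sensitivity/specificity,
  boundary noise, per-modality misregistration), so the whole pipeline is
  testable without patient data.
* I/O for NIfTI-1 (`.nii`/`.nii.gz`) and NRRD masks, tidy CSV records and
  summary tables in the standard median (min, max) cohort layout, and a thin CLI
  (`inst/cli/gtvhisto.R`: `simulate`, `fuse`, `evaluate`, `calibrate`,
  `report`) over a shared YAML configuration.

See the methods vignette (`vignettes/gtvhisto-methods.Rmd`) for the model
details, parameter choices and limitations.

## Worked example

Simulate a small cohort, build every GTV definition, and summarize:

```r
library(gtvhisto)

cfg    <- cohort_config(n_patients = 4, seed = 11)
cohort <- generate_cohort(cfg)

rec  <- evaluate_cohort(cohort, staple_params(), margins_mm = c(0, 2))
summ <- summarize_cohort(rec)
subset(summ, gtv_name %in% c("T2w", "mpMRI") & metric == "dsc")
#>  gtv_name     source margin_mm metric centre    lo    hi n
#>     mpMRI individual         0    dsc  0.680 0.672 0.693 4
#>     mpMRI individual         2    dsc  0.333 0.315 0.342 4
#>       T2w individual         0    dsc  0.717 0.691 0.754 4
#>       T2w individual         2    dsc  0.521 0.472 0.565 4
#>     mpMRI     staple         0    dsc  0.725 0.652 0.767 4
#>     mpMRI     staple         2    dsc  0.428 0.387 0.641 4
#>       T2w     staple         0    dsc  0.828 0.755 0.831 4
#>       T2w     staple         2    dsc  0.635 0.615 0.733 4
```

`staple` rows are the median (min, max) over patients of the STAPLE-fused
GTVs; `individual` rows aggregate the four observers' per-observer medians
(mean, with min and max median), quantifying interobserver variability.
Adding a CTV margin grows coverage but dilutes DSC with healthy tissue —
visible above as the margin-2 mm DSC drop.

Single patients work the same way:

```r
d <- cohort$P01
d
#> <delineation_set> patient P01: 4 observers x {T2w, DWI, DCE, PSMA-PET}, lesion 1.12 ml

gtv <- fuse_multi_modality(d, c("T2w", "DWI", "DCE"))   # mpMRI GTV
mask_volume_ml(gtv)                                     # 1.88 ml
dice(gtv, d$histo_lesion)                               # 0.747
lesion_coverage(gtv, d$histo_lesion)                    # 1.000

optimize_translation(gtv, d$histo_lesion, lambda = 0.002)
#> <alignment_result> t = (0.00, 0.00) mm (|t| = 0.000), DSC 0.747 -> 0.747, lambda 0.002
```

Here the fused GTV covers the lesion completely and is already optimally
aligned, so the penalized registration keeps it in place.

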