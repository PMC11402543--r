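# One patient's delineation data and the study's GTV construction schemes:
# per-image-type STAPLE over observers, union-then-STAPLE over multiple image
# types, and per-observer union GTVs. Every fused GTV is thresholded at tau
# and cropped to the histopathology support.

#' One patient's observer x image-type delineations plus histopathology
#'
#' @param patient_id Identifier string.
#' @param masks Nested named list: `masks[[observer]][[image_type]]` is a
#'   [binary_mask()]. All masks must share one grid (resample on load with
#'   [resample_nearest()] if needed).
#' @param histo_lesion Ground-truth lesion mask (the Gleason-4/5 target
#'   region) on the same grid.
#' @param histo_support Histopathology support mask (where ground truth
#'   exists); `histo_lesion` must be contained in it.
#' @param truth_params Optional record of generating parameters (synthetic
#'   cohorts only), kept for validation.
#' @return A `delineation_set`.
#' @export
delineation_set <- function(patient_id, masks, histo_lesion, histo_support,
                            truth_params = NULL) {
  if (length(masks) == 0L) stop("`masks` must be non-empty", call. = FALSE)
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("`masks` must be named by observer", call. = FALSE)
  ref <- histo_support
  stop_if_grid_mismatch(histo_lesion, ref, "lesion and support")
  if (any(histo_lesion$values & !histo_support$values))
    stop("`histo_lesion` must be contained in `histo_support`", call. = FALSE)
  for (obs in names(masks)) {
    if (is.null(names(masks[[obs]])) || length(masks[[obs]]) == 0L)
      stop(sprintf("observer '%s' has no named image-type masks", obs),
           call. = FALSE)
    for (m in masks[[obs]]) stop_if_grid_mismatch(ref, m, "delineation masks")
  }
  structure(list(patient_id = patient_id, masks = masks,
                 histo_lesion = histo_lesion, histo_support = histo_support,
                 truth_params = truth_params),
            class = "delineation_set")
}

#' @export
print.delineation_set <- function(x, ...) {
  cat(sprintf("<delineation_set> patient %s: %d observers x {%s}, lesion %.2f ml\n",
              x$patient_id, length(x$masks),
              paste(unique(unlist(lapply(x$masks, names))), collapse = ", "),
              mask_volume_ml(x$histo_lesion)))
  invisible(x)
}

#' @rdname delineation_set
#' @param dset A `delineation_set`.
#' @export
observers <- function(dset) names(dset$masks)

#' @rdname delineation_set
#' @export
image_types <- function(dset) unique(unlist(lapply(dset$masks, names)))

get_observer_mask <- function(dset, observer, image_type) {
  if (!observer %in% names(dset$masks))
    stop(sprintf("unknown observer '%s'", observer), call. = FALSE)
  m <- dset$masks[[observer]][[image_type]]
  if (is.null(m))
    stop(sprintf("observer '%s' has no mask for image type '%s'",
                 observer, image_type), call. = FALSE)
  m
}

#' Single-modality STAPLE GTV
#'
#' Fuses all observers' delineations of one image type with [staple_em()],
#' thresholds the posterior at `params$threshold` and crops the result to the
#' histopathology support. Applied to T2w, DWI, DCE and PSMA-PET in turn this
#' yields the four single-modality GTVs of the analysis.
#'
#' @param dset A [delineation_set()]; every observer must have a mask for
#'   `image_type`.
#' @param image_type Modality label, e.g. `"T2w"`.
#' @param params A [staple_params()].
#' @return A [binary_mask()].
#' @export
fuse_single_modality <- function(dset, image_type, params = staple_params()) {
  fuse_multi_modality(dset, image_type, params)
}

#' Multi-modality union-then-STAPLE GTV
#'
#' The two-step combination scheme for GTVs spanning several image types:
#' first each observer's delineations of the requested image types are merged
#' into a per-observer union, then the four per-observer unions are fused
#' with [staple_em()], thresholded at `params$threshold` and cropped to the
#' histopathology support. With `image_types = c("T2w", "DWI")` this is the
#' bpMRI GTV, adding DCE gives mpMRI, and all four types give PSMA-PET/mpMRI.
#' Requesting a single image type reduces exactly to [fuse_single_modality()].
#'
#' @param dset A [delineation_set()].
#' @param image_types Non-empty character vector of modality labels; every
#'   observer must have a mask for each.
#' @param params A [staple_params()].
#' @return A [binary_mask()].
#' @export
fuse_multi_modality <- function(dset, image_types, params = staple_params()) {
  if (length(image_types) == 0L)
    stop("`image_types` must be non-empty", call. = FALSE)
  unions <- lapply(names(dset$masks), function(obs)
    mask_union(lapply(image_types, function(ty) get_observer_mask(dset, obs, ty))))
  names(unions) <- names(dset$masks)
  fused <- staple_em(unions, params)
  crop_to_support(threshold_posterior(fused, params$threshold),
                  dset$histo_support)
}

#' Individual-observer union GTV
#'
#' One observer's combined GTV: the union of that observer's delineations
#' across image types (all of them by default), cropped to the histopathology
#' support. These per-observer volumes quantify interobserver variability.
#'
#' @param dset A [delineation_set()].
#' @param observer Observer id (a name of `dset$masks`).
#' @param image_types Modality labels to combine; defaults to every type the
#'   observer delineated.
#' @return A [binary_mask()].
#' @export
observer_union_gtv <- function(dset, observer, image_types = NULL) {
  if (!observer %in% names(dset$masks))
    stop(sprintf("unknown observer '%s'", observer), call. = FALSE)
  if (is.null(image_types)) image_types <- names(dset$masks[[observer]])
  u <- mask_union(lapply(image_types, function(ty)
    get_observer_mask(dset, observer, ty)))
  crop_to_support(u, dset$histo_support)
}

# canonical multi-modality combinations of the four study image types
gtv_combinations <- function() {
  list("bpMRI" = c("T2w", "DWI"),
       "mpMRI" = c("T2w", "DWI", "DCE"),
       "PSMA-PET/mpMRI" = c("T2w", "DWI", "DCE", "PSMA-PET"))
}

#' Build the full set of STAPLE GTVs for one patient
#'
#' The four single-modality GTVs plus every canonical multi-modality
#' combination whose image types are all present in the data (bpMRI, mpMRI,
#' PSMA-PET/mpMRI).
#'
#' @param dset A [delineation_set()].
#' @param params A [staple_params()].
#' @return Named list of [binary_mask()] GTVs.
#' @export
build_staple_gtvs <- function(dset, params = staple_params()) {
  types <- image_types(dset)
  gtvs <- lapply(types, function(ty) fuse_single_modality(dset, ty, params))
  names(gtvs) <- types
  for (nm in names(gtv_combinations())) {
    combo <- gtv_combinations()[[nm]]
    if (all(combo %in% types))
      gtvs[[nm]] <- fuse_multi_modality(dset, combo, params)
  }
  gtvs
}

#' Build one observer's individual GTVs
#'
#' Single image types are the observer's own delineations cropped to the
#' support; multi-modality entries are that observer's unions (no STAPLE is
#' involved for individual GTVs).
#'
#' @param dset A [delineation_set()].
#' @param observer Observer id.
#' @return Named list of [binary_mask()] GTVs, same names as
#'   [build_staple_gtvs()].
#' @export
build_individual_gtvs <- function(dset, observer) {
  types <- names(dset$masks[[observer]])
  gtvs <- lapply(types, function(ty)
    crop_to_support(get_observer_mask(dset, observer, ty), dset$histo_support))
  names(gtvs) <- types
  for (nm in names(gtv_combinations())) {
    combo <- gtv_combinations()[[nm]]
    if (all(combo %in% types))
      gtvs[[nm]] <- observer_union_gtv(dset, observer, combo)
  }
  gtvs
}

#' All-MRI, all-observer calibration GTV
#'
#' The combined GTV used to calibrate the translation-penalty weight: the
#' union-then-STAPLE combination over the MRI image types (T2w, DWI, DCE) and
#' all observers.
#'
#' @param dset A [delineation_set()].
#' @param params A [staple_params()].
#' @param mri_types MRI modality labels.
#' @return A [binary_mask()].
#' @export
calibration_gtv <- function(dset, params = staple_params(),
                            mri_types = c("T2w", "DWI", "DCE")) {
  fuse_multi_modality(dset, mri_types, params)
}
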