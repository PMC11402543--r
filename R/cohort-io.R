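# Cohort persistence: masks as NIfTI/NRRD volumes plus a manifest CSV and a
# generating-truth JSON, so simulated cohorts can be exchanged with other
# tools and reloaded.

#' Write a cohort to a directory
#'
#' Writes every observer mask, the histopathology lesion and support of each
#' patient as volumetric files, a `manifest.csv` indexing them, and (for
#' synthetic cohorts) a `truth.json` with the generating parameters.
#'
#' @param cohort Named list of [delineation_set()] patients.
#' @param dir Output directory (created if missing).
#' @param format `"nifti"` or `"nrrd"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truth <- list()
  for (dset in cohort) {
    pdir <- file.path(dir, dset$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    add <- function(role, observer, image_type, mask, fname) {
      write_mask(mask, file.path(pdir, fname), format)
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = dset$patient_id, role = role, observer = observer,
        image_type = image_type,
        path = file.path(dset$patient_id, fname), stringsAsFactors = FALSE)
    }
    for (obs in observers(dset))
      for (ty in names(dset$masks[[obs]]))
        add("delineation", obs, ty, dset$masks[[obs]][[ty]],
            paste0(obs, "_", gsub("[^A-Za-z0-9]", "-", ty), ext))
    add("histo_lesion", NA, NA, dset$histo_lesion, paste0("histo_lesion", ext))
    add("histo_support", NA, NA, dset$histo_support,
        paste0("histo_support", ext))
    tp <- dset$truth_params
    if (!is.null(tp)) {
      tp$lesion <- NULL   # the mask itself is not serialized to JSON
      truth[[dset$patient_id]] <- tp
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (length(truth) > 0L)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Masks are reloaded and resampled onto each patient's histopathology
#' support grid with [resample_nearest()] (a no-op when grids already
#' match), per the convention that all analysis happens on the reference
#' grid.
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return Named list of [delineation_set()] patients.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path))
    stop(sprintf("no manifest.csv in '%s'", dir), call. = FALSE)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  cohort <- list()
  for (pid in unique(mf$patient_id)) {
    sub <- mf[mf$patient_id == pid, , drop = FALSE]
    get1 <- function(role) {
      r <- sub[sub$role == role, , drop = FALSE]
      if (nrow(r) != 1L)
        stop(sprintf("patient %s: expected exactly one %s", pid, role),
             call. = FALSE)
      read_mask(file.path(dir, r$path))
    }
    support <- get1("histo_support")
    lesion <- resample_nearest(get1("histo_lesion"), support$grid)
    dl <- sub[sub$role == "delineation", , drop = FALSE]
    masks <- list()
    for (i in seq_len(nrow(dl))) {
      m <- resample_nearest(read_mask(file.path(dir, dl$path[i])),
                            support$grid)
      masks[[dl$observer[i]]][[dl$image_type[i]]] <- m
    }
    cohort[[pid]] <- delineation_set(pid, masks, lesion, support)
  }
  cohort
}
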