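# Voxel-wise agreement metrics between GTVs and the histopathology lesion.

#' Dice similarity coefficient
#'
#' \eqn{DSC(A, B) = 2|A \cap B| / (|A| + |B|)}. Comparing two empty masks is
#' an error rather than a convention value: the pipeline never produces that
#' comparison legitimately, so a silent 0 or 1 would hide upstream bugs.
#'
#' @param a,b [binary_mask()] objects on one grid, not both empty.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na == 0L && nb == 0L)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Lesion coverage (voxel-wise sensitivity)
#'
#' The fraction of the histopathology lesion contained in the GTV:
#' \eqn{|GTV \cap L| / |L|}.
#'
#' @param gtv A [binary_mask()].
#' @param lesion A non-empty [binary_mask()] on the same grid.
#' @return Coverage in \[0, 1\].
#' @export
lesion_coverage <- function(gtv, lesion) {
  stop_if_grid_mismatch(gtv, lesion, "gtv and lesion")
  nl <- sum(lesion$values)
  if (nl == 0L)
    stop("lesion coverage is undefined for an empty lesion", call. = FALSE)
  sum(gtv$values & lesion$values) / nl
}

#' Evaluate a set of GTVs against the lesion across CTV margins
#'
#' For every (GTV, margin) pair: the GTV is optionally shifted (registration
#' experiment), expanded by the isotropic margin with [expand_margin()],
#' cropped to the histopathology support, and compared with the lesion by
#' [dice()] and [lesion_coverage()]. Returns one tidy row per pair.
#'
#' @param gtvs Named list of [binary_mask()] GTVs.
#' @param lesion Non-empty ground-truth lesion [binary_mask()].
#' @param support Histopathology support [binary_mask()].
#' @param margins_mm Non-negative margin radii in mm (study values 0:3).
#' @param patient_id Identifier recorded in the output.
#' @param source `"staple"` or `"individual"`.
#' @param observer Observer id for individual GTVs, `NA` for STAPLE.
#' @param shift_mm Optional in-plane (y, x) translation in mm applied to each
#'   GTV before expansion.
#' @return data.frame with columns patient_id, gtv_name, source, observer,
#'   margin_mm, dsc, coverage, gtv_volume_ml, lesion_volume_ml.
#' @export
evaluate_case <- function(gtvs, lesion, support, margins_mm = c(0, 1, 2, 3),
                          patient_id = "patient", source = "staple",
                          observer = NA_character_, shift_mm = NULL) {
  if (length(gtvs) == 0L) stop("`gtvs` must be non-empty", call. = FALSE)
  if (is.null(names(gtvs))) stop("`gtvs` must be named", call. = FALSE)
  if (any(margins_mm < 0)) stop("margins must be non-negative", call. = FALSE)
  lesion_ml <- mask_volume_ml(lesion)
  rows <- vector("list", length(gtvs) * length(margins_mm))
  k <- 0L
  for (nm in names(gtvs)) {
    g <- gtvs[[nm]]
    if (!is.null(shift_mm)) g <- shift_mask(g, shift_mm)
    for (r in margins_mm) {
      ctv <- crop_to_support(expand_margin(g, r), support)
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = patient_id, gtv_name = nm, source = source,
        observer = observer, margin_mm = r,
        dsc = dice(ctv, lesion), coverage = lesion_coverage(ctv, lesion),
        gtv_volume_ml = mask_volume_ml(ctv), lesion_volume_ml = lesion_ml,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
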