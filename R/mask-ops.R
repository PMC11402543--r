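# Binary-mask algebra: union, cropping, nearest-neighbour resampling and
# integer translation. All operations preserve the voxel-centre convention
# declared in voxel_grid().

#' Voxelwise union of masks
#'
#' Logical OR of a list of masks sharing one grid. Callers resample onto a
#' common reference grid first (see [resample_nearest()]).
#'
#' @param masks Non-empty list of [binary_mask()] objects on one grid.
#' @return A [binary_mask()] on the shared grid.
#' @export
mask_union <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("`masks` must be a non-empty list of binary masks", call. = FALSE)
  ref <- masks[[1L]]
  for (m in masks[-1L]) stop_if_grid_mismatch(ref, m)
  v <- Reduce(`|`, lapply(masks, `[[`, "values"))
  binary_mask(v, ref$grid)
}

#' Crop a mask to a support region
#'
#' Voxelwise AND with a support mask: used to restrict GTVs to the region
#' where ground-truth histopathology exists, so extraprostatic voxels never
#' enter the overlap metrics.
#'
#' @param mask,support [binary_mask()] objects on one grid.
#' @return A [binary_mask()]; a subset of both inputs.
#' @export
crop_to_support <- function(mask, support) {
  stop_if_grid_mismatch(mask, support, "mask and support")
  binary_mask(mask$values & support$values, mask$grid)
}

#' Nearest-neighbour resampling onto a reference grid
#'
#' Each output voxel takes the value of the input voxel whose centre is
#' nearest (in physical mm) to the output voxel's centre; output voxels whose
#' nearest input centre lies outside the input lattice are background.
#' Distance ties are resolved towards the lower index. Resampling a mask onto
#' its own grid is the identity.
#'
#' @param mask A [binary_mask()].
#' @param reference Target [voxel_grid()].
#' @return A [binary_mask()] on `reference`.
#' @export
resample_nearest <- function(mask, reference) {
  if (!inherits(reference, "voxel_grid"))
    stop("`reference` must be a voxel_grid", call. = FALSE)
  out <- array(FALSE, dim = reference$shape)
  idx <- vector("list", 3L)
  keep <- vector("list", 3L)
  for (a in 1:3) {
    u <- (axis_coords(reference, a) - mask$grid$origin_mm[a]) /
      mask$grid$spacing_mm[a]
    # nearest 0-based index, ties to the lower index
    i <- as.integer(ceiling(u - 0.5)) + 1L
    keep[[a]] <- which(i >= 1L & i <= mask$grid$shape[a])
    idx[[a]] <- i[keep[[a]]]
  }
  if (all(lengths(keep) > 0L)) {
    out[keep[[1L]], keep[[2L]], keep[[3L]]] <-
      mask$values[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  }
  binary_mask(out, reference)
}

# Shift a logical array by an integer number of voxels per axis, filling with
# FALSE. d = (dk, dj, di): content moves towards higher indices for d > 0.
translate_values <- function(values, d) {
  dm <- dim(values)
  out <- array(FALSE, dim = dm)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    n <- dm[a]
    lo <- max(1L, 1L + d[a]); hi <- min(n, n + d[a])
    if (lo > hi) return(out)
    dst[[a]] <- lo:hi
    src[[a]] <- (lo - d[a]):(hi - d[a])
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    values[src[[1L]], src[[2L]], src[[3L]], drop = FALSE]
  out
}

# Physical translation (mm) -> integer voxel displacement under the package's
# nearest-centre convention (half-voxel offsets round away from the lower
# index, consistent with resample_nearest).
voxel_displacement <- function(translation_mm, spacing_mm) {
  as.integer(floor(translation_mm / spacing_mm + 0.5))
}

#' Shift a mask by a physical translation
#'
#' Translates mask content by `translation_mm`, given as (y, x) for an
#' in-plane shift or (z, y, x). Under the nearest-neighbour model the content
#' moves by the integer voxel displacement nearest to
#' `translation_mm / spacing`; voxels shifted beyond the grid are lost and
#' vacated voxels become background.
#'
#' @param mask A [binary_mask()].
#' @param translation_mm Numeric length 2 (y, x) or length 3 (z, y, x), mm.
#' @return A shifted [binary_mask()] on the same grid.
#' @export
shift_mask <- function(mask, translation_mm) {
  t3 <- switch(as.character(length(translation_mm)),
               "2" = c(0, translation_mm), "3" = translation_mm,
               stop("`translation_mm` must have length 2 or 3", call. = FALSE))
  d <- voxel_displacement(t3, mask$grid$spacing_mm)
  binary_mask(translate_values(mask$values, d), mask$grid)
}
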