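# Isotropic CTV margin expansion in physical millimetres on possibly
# anisotropic grids.

# all integer voxel offsets whose physical length is <= radius_mm
margin_offsets <- function(spacing_mm, radius_mm) {
  reach <- floor(radius_mm / spacing_mm + 1e-9)
  ks <- -reach[1L]:reach[1L]
  js <- -reach[2L]:reach[2L]
  is <- -reach[3L]:reach[3L]
  off <- expand.grid(dk = ks, dj = js, di = is, KEEP.OUT.ATTRS = FALSE)
  d2 <- (off$dk * spacing_mm[1L])^2 + (off$dj * spacing_mm[2L])^2 +
    (off$di * spacing_mm[3L])^2
  off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Isotropic margin expansion (GTV to CTV)
#'
#' Expands the mask so that the output contains every voxel whose centre lies
#' within Euclidean distance `radius_mm` (physical mm, spacing-aware) of some
#' foreground voxel centre of the input. Radius 0 is the identity. On
#' anisotropic grids the expansion respects physical distance: with 5 mm
#' slices a 3 mm margin never leaves the slice.
#'
#' Implemented as binary dilation with the set of integer voxel offsets of
#' physical length at most `radius_mm`, which is exact for this definition.
#'
#' @param mask A [binary_mask()].
#' @param radius_mm Non-negative margin radius in mm.
#' @return An expanded [binary_mask()] containing the input.
#' @export
expand_margin <- function(mask, radius_mm) {
  if (length(radius_mm) != 1L || !is.finite(radius_mm) || radius_mm < 0)
    stop("`radius_mm` must be a non-negative real", call. = FALSE)
  if (radius_mm == 0 || !any(mask$values)) return(mask)
  off <- margin_offsets(mask$grid$spacing_mm, radius_mm)
  out <- mask$values
  for (r in seq_len(nrow(off))) {
    d <- c(off$dk[r], off$dj[r], off$di[r])
    if (all(d == 0L)) next
    out <- out | translate_values(mask$values, d)
  }
  binary_mask(out, mask$grid)
}
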