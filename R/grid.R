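#' Regular 3D voxel grid geometry
#'
#' A `voxel_grid` describes a regular, axis-aligned 3D lattice: its shape in
#' voxels, voxel spacing in millimetres and the physical position of the
#' centre of the first voxel. Axis order is (slice, row, column), i.e.
#' (z, y, x), throughout the package, and the voxel-centre convention is used:
#' voxel index \eqn{(k, j, i)} (0-based) sits at physical position
#' \eqn{origin + (k, j, i) \odot spacing}.
#'
#' @param shape Integer vector of length 3, voxel counts per axis
#'   (slices, rows, cols); every entry must be >= 1.
#' @param spacing_mm Positive numeric vector of length 3, voxel spacing in mm
#'   per axis (z, y, x).
#' @param origin_mm Numeric vector of length 3, physical position (mm) of the
#'   centre of voxel (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(24, 96, 96), c(2.5, 1, 1))
#' voxel_volume_mm3(g)
#' @export
voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1) ||
      any(shape != round(shape)))
    stop("`shape` must be three integers >= 1", call. = FALSE)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive reals", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be three finite reals", call. = FALSE)
  structure(
    list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$spacing_mm), collapse = ", "),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing_mm)

#' Test two grids for equality
#'
#' Shapes must match exactly; spacing and origin to within `tol` mm.
#'
#' @param a,b `voxel_grid` objects.
#' @param tol Geometric tolerance in mm.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

# physical centre coordinates of all voxels along one axis (1 = slice/z)
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}

stop_if_grid_mismatch <- function(a, b, what = "masks") {
  if (!grid_equal(a$grid, b$grid))
    stop(sprintf("%s are on different voxel grids", what), call. = FALSE)
  invisible(NULL)
}

#' Binary segmentation mask on a voxel grid
#'
#' The universal currency of the pipeline: a boolean field over a
#' [voxel_grid()]. Numeric input is binarized (non-zero = foreground).
#'
#' @param values Logical (or numeric) 3D array whose dimensions equal
#'   `grid$shape`.
#' @param grid A [voxel_grid()].
#' @return An object of class `binary_mask`.
#' @seealso [mask_volume_ml()], [mask_union()], [crop_to_support()]
#' @export
binary_mask <- function(values, grid) {
  if (!inherits(grid, "voxel_grid")) stop("`grid` must be a voxel_grid", call. = FALSE)
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("`values` dimensions do not match the grid shape", call. = FALSE)
  v <- if (is.logical(values)) values else values != 0
  v[is.na(v)] <- FALSE
  dim(v) <- grid$shape
  structure(list(grid = grid, values = v), class = "binary_mask")
}

#' @rdname binary_mask
#' @export
empty_mask <- function(grid) {
  binary_mask(array(FALSE, dim = grid$shape), grid)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.3f ml)\n",
              paste(x$grid$shape, collapse = " x "),
              sum(x$values), mask_volume_ml(x)))
  invisible(x)
}

#' Foreground volume in millilitres
#'
#' Foreground voxel count times the physical voxel volume, in ml.
#'
#' @param mask A [binary_mask()].
#' @return Volume in ml.
#' @examples
#' g <- voxel_grid(c(4, 10, 10), c(5, 1, 1))
#' m <- empty_mask(g); m$values[1, 1:10, 1:10] <- TRUE
#' mask_volume_ml(m)  # 100 voxels x 5 mm^3 = 0.5 ml
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$values) * voxel_volume_mm3(mask$grid) / 1000
}
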