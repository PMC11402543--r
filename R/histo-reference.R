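# Ground-truth construction from per-slice histopathology delineations:
# delineations overlapping in-plane on consecutive slices belong to one
# lesion; the target mask is the largest lesion restricted to Gleason
# pattern 4/5 voxels.

#' A single-slice histopathology delineation
#'
#' @param slice_index 1-based slice index on the reference grid.
#' @param region 2D logical (rows x cols) field marking the delineated area
#'   on that slice.
#' @param gleason_pattern Integer Gleason pattern of the region: 3, 4 or 5.
#' @return A `slice_delineation`.
#' @export
slice_delineation <- function(slice_index, region, gleason_pattern) {
  if (length(slice_index) != 1L || slice_index < 1 ||
      slice_index != round(slice_index))
    stop("`slice_index` must be a positive integer", call. = FALSE)
  if (is.null(dim(region)) || length(dim(region)) != 2L)
    stop("`region` must be a 2D array", call. = FALSE)
  if (!gleason_pattern %in% c(3L, 4L, 5L))
    stop("`gleason_pattern` must be 3, 4 or 5", call. = FALSE)
  structure(list(slice_index = as.integer(slice_index),
                 region = region != 0,
                 gleason_pattern = as.integer(gleason_pattern)),
            class = "slice_delineation")
}

#' Merge per-slice delineations into 3D lesions
#'
#' Two delineations belong to the same lesion iff they are connected by a
#' chain of delineation pairs on consecutive slices whose regions share at
#' least one in-plane voxel. Delineations on the same slice are never merged
#' directly (even if they overlap in-plane) but may be bridged through other
#' slices. Lesion ids are assigned in a canonical order (lowest slice, then
#' lowest in-plane voxel index), so the labeling does not depend on the input
#' ordering.
#'
#' @param delineations Non-empty list of [slice_delineation()] objects.
#' @param grid The reference [voxel_grid()]; slice indices and region shapes
#'   must fit it.
#' @return A `lesion_labeling`: list with `labels` (integer array on `grid`,
#'   0 = background), `lesion_count`, and `assignment` (lesion id per input
#'   delineation).
#' @export
merge_lesions_z <- function(delineations, grid) {
  n <- length(delineations)
  if (n == 0L) stop("`delineations` must be non-empty", call. = FALSE)
  for (d in delineations) {
    if (!inherits(d, "slice_delineation"))
      stop("all elements must be slice_delineation objects", call. = FALSE)
    if (d$slice_index > grid$shape[1L])
      stop(sprintf("slice index %d outside the grid (%d slices)",
                   d$slice_index, grid$shape[1L]), call. = FALSE)
    if (!identical(as.integer(dim(d$region)), grid$shape[2:3]))
      stop("delineation region shape does not match the grid", call. = FALSE)
  }
  # union-find over delineations
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  slices <- vapply(delineations, `[[`, integer(1L), "slice_index")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(slices[i] - slices[j]) != 1L) next
      if (any(delineations[[i]]$region & delineations[[j]]$region)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  # canonical lesion order: lexicographic over the component's full sorted
  # voxel set (slice-major), so the labeling is independent of input order
  comp_ids <- unique(root)
  plane <- prod(grid$shape[2:3])
  key <- vapply(comp_ids, function(r) {
    members <- which(root == r)
    vox <- sort(unique(unlist(lapply(members, function(m)
      (slices[m] - 1L) * plane + which(delineations[[m]]$region)))))
    paste(sprintf("%09d", vox), collapse = ",")
  }, character(1L))
  ord <- order(key)
  lesion_of_root <- integer(max(comp_ids))
  lesion_of_root[comp_ids[ord]] <- seq_along(comp_ids)
  assignment <- lesion_of_root[root]

  labels <- array(0L, dim = grid$shape)
  # paint highest lesion id first so lower ids win voxel conflicts
  for (i in order(assignment, decreasing = TRUE)) {
    sl <- slices[i]
    plane <- labels[sl, , ]
    plane[delineations[[i]]$region] <- assignment[i]
    labels[sl, , ] <- plane
  }
  structure(list(labels = labels, lesion_count = length(comp_ids),
                 assignment = assignment, grid = grid),
            class = "lesion_labeling")
}

#' @export
print.lesion_labeling <- function(x, ...) {
  cat(sprintf("<lesion_labeling> %d lesion(s), %d labelled voxels\n",
              x$lesion_count, sum(x$labels > 0L)))
  invisible(x)
}

#' Target lesion mask: largest Gleason-filtered lesion
#'
#' Restricts each lesion to the voxels of delineations whose Gleason pattern
#' is in `grade_filter` (patterns 4 and 5 by default) and returns the lesion
#' with the largest filtered volume — the operational definition of the
#' dominant intraprostatic lesion. Ties go to the lower lesion id.
#'
#' @param labeling A `lesion_labeling` from [merge_lesions_z()].
#' @param delineations The same list of [slice_delineation()] objects the
#'   labeling was built from.
#' @param grade_filter Non-empty set of Gleason patterns to keep.
#' @return A [binary_mask()] of the selected lesion's filtered voxels.
#' @export
target_lesion_mask <- function(labeling, delineations, grade_filter = c(4, 5)) {
  if (length(grade_filter) == 0L)
    stop("`grade_filter` must be non-empty", call. = FALSE)
  if (length(delineations) != length(labeling$assignment))
    stop("`delineations` does not match the labeling", call. = FALSE)
  grid <- labeling$grid
  filtered <- array(FALSE, dim = grid$shape)   # per-lesion accumulation
  lesion_vox <- vector("list", labeling$lesion_count)
  for (i in seq_along(delineations)) {
    d <- delineations[[i]]
    if (!d$gleason_pattern %in% grade_filter) next
    lid <- labeling$assignment[i]
    plane <- array(FALSE, dim = grid$shape[2:3])
    plane[d$region] <- TRUE
    idx <- which(plane)
    if (length(idx) == 0L) next
    # linear indices on the full grid for slice d$slice_index
    full <- d$slice_index + (idx - 1L) * grid$shape[1L]
    lesion_vox[[lid]] <- union(lesion_vox[[lid]], full)
  }
  counts <- vapply(lesion_vox, length, integer(1L))
  if (all(counts == 0L))
    stop("no lesion contains voxels passing the Gleason grade filter",
         call. = FALSE)
  best <- which.max(counts)
  out <- array(FALSE, dim = grid$shape)
  out[lesion_vox[[best]]] <- TRUE
  binary_mask(out, grid)
}
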