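# Synthetic cohort generator: desk-scale patients with the statistical
# structure the validation analysis assumes — an ellipsoidal gland (the
# histopathology support), a blob-shaped lesion with log-uniform Gleason-4/5
# volume, four observers x four image types drawn from the STAPLE generative
# model (sensitivity p inside the truth, false positives at rate 1-q confined
# to a shell around the lesion), per-(observer, image type)
# over/under-segmentation boundary noise, and per-image-type in-plane
# misregistration translations.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions: 15 patients, a 24 x 96 x 96 grid at
#' (2.5, 1, 1) mm, lesion volumes spanning 0.22-11.22 ml (log-uniform), four
#' observers and four image types, and per-image-type in-plane
#' misregistration with expected displacement ~1.7 mm.
#'
#' @param n_patients Number of patients.
#' @param shape,spacing_mm,origin_mm Reference grid specification
#'   (slices, rows, cols) / (z, y, x) mm.
#' @param lesion_volume_range_ml Ordered positive pair: lesion volumes are
#'   drawn log-uniformly from this range (ml).
#' @param n_observers Number of delineating observers.
#' @param image_types Modality labels.
#' @param sensitivity_range,specificity_range Per-image-type probability
#'   pairs in (0.5, 1] (a single pair is recycled to all types): each
#'   observer's per-type sensitivity/specificity is drawn uniformly from the
#'   corresponding range.
#' @param boundary_noise_mm Standard deviation (mm) of the per-(observer,
#'   image type) over/under-segmentation of the lesion boundary; 0 disables.
#' @param misregistration_sd_mm Per-axis SD (mm) of the per-image-type
#'   in-plane misregistration translation; the default makes the expected
#'   displacement norm equal 1.7 mm (Rayleigh mean sd*sqrt(pi/2)).
#' @param gleason4or5_fraction Fraction of the lesion labelled Gleason
#'   pattern 4/5 (a connected sub-region); the remainder is pattern 3.
#' @param fp_shell_mm Width (mm) of the shell around the lesion within which
#'   false positives may occur.
#' @param seed Master seed; per-patient streams are derived from it.
#' @param noiseless If TRUE, switch off every discrepancy source (p = q = 1,
#'   no boundary noise, no misregistration, Gleason fraction 1): the whole
#'   downstream pipeline is then exact.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 15L,
                          shape = c(24L, 96L, 96L),
                          spacing_mm = c(2.5, 1, 1),
                          origin_mm = c(0, 0, 0),
                          lesion_volume_range_ml = c(0.22, 11.22),
                          n_observers = 4L,
                          image_types = c("T2w", "DWI", "DCE", "PSMA-PET"),
                          sensitivity_range = list(
                            "T2w" = c(0.75, 0.90), "DWI" = c(0.75, 0.90),
                            "DCE" = c(0.60, 0.80), "PSMA-PET" = c(0.70, 0.90)),
                          specificity_range = c(0.95, 0.99),
                          boundary_noise_mm = 0.5,
                          misregistration_sd_mm = 1.7 / sqrt(pi / 2),
                          gleason4or5_fraction = 0.85,
                          fp_shell_mm = 5,
                          seed = 1L,
                          noiseless = FALSE) {
  if (noiseless) {
    sensitivity_range <- c(1, 1); specificity_range <- c(1, 1)
    boundary_noise_mm <- 0; misregistration_sd_mm <- 0
    gleason4or5_fraction <- 1
  }
  grid <- voxel_grid(shape, spacing_mm, origin_mm)
  norm_ranges <- function(r, what) {
    if (!is.list(r)) r <- stats::setNames(rep(list(r), length(image_types)),
                                          image_types)
    for (ty in image_types) {
      v <- r[[ty]]
      if (is.null(v) || length(v) != 2L || v[1L] > v[2L] ||
          v[1L] <= 0.5 || v[2L] > 1)
        stop(sprintf("%s for '%s' must be an ordered pair in (0.5, 1]",
                     what, ty), call. = FALSE)
    }
    r[image_types]
  }
  if (length(lesion_volume_range_ml) != 2L ||
      any(lesion_volume_range_ml <= 0) ||
      lesion_volume_range_ml[1L] > lesion_volume_range_ml[2L])
    stop("`lesion_volume_range_ml` must be an ordered positive pair",
         call. = FALSE)
  if (gleason4or5_fraction <= 0 || gleason4or5_fraction > 1)
    stop("`gleason4or5_fraction` must lie in (0, 1]", call. = FALSE)
  if (boundary_noise_mm < 0 || misregistration_sd_mm < 0 || fp_shell_mm < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  if (n_patients < 1 || n_observers < 1)
    stop("`n_patients` and `n_observers` must be >= 1", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients), grid = grid,
    lesion_volume_range_ml = lesion_volume_range_ml,
    n_observers = as.integer(n_observers), image_types = image_types,
    sensitivity_range = norm_ranges(sensitivity_range, "sensitivity_range"),
    specificity_range = norm_ranges(specificity_range, "specificity_range"),
    boundary_noise_mm = boundary_noise_mm,
    misregistration_sd_mm = misregistration_sd_mm,
    gleason4or5_fraction = gleason4or5_fraction,
    fp_shell_mm = fp_shell_mm, seed = as.integer(seed)),
    class = "cohort_config")
}

# morphological erosion by physical radius: complement-dilate-complement
erode_margin <- function(mask, radius_mm) {
  if (radius_mm == 0) return(mask)
  inv <- binary_mask(!mask$values, mask$grid)
  binary_mask(!expand_margin(inv, radius_mm)$values, mask$grid)
}

# separable Gaussian bump evaluated on the grid (centre and per-axis sigma in
# mm): weight * exp(-0.5 * sum(((x - c)/sigma)^2))
gaussian_field <- function(grid, centre, sigma, weight = 1) {
  ez <- exp(-0.5 * ((axis_coords(grid, 1L) - centre[1L]) / sigma[1L])^2)
  ey <- exp(-0.5 * ((axis_coords(grid, 2L) - centre[2L]) / sigma[2L])^2)
  ex <- exp(-0.5 * ((axis_coords(grid, 3L) - centre[3L]) / sigma[3L])^2)
  weight * (ez %o% ey %o% ex)
}

# grow a connected sub-region of `target_n` voxels inside `region_idx`
# (linear indices), seeded at the highest-field voxel, expanding 6-connected
# neighbours in decreasing field order (compact, connected by construction)
grow_subregion <- function(field, region_idx, target_n, shape) {
  pos <- arrayInd(region_idx, shape)
  local_id <- array(0L, dim = shape)
  local_id[region_idx] <- seq_along(region_idx)
  nbr_of <- function(i) {
    p <- pos[i, ]
    out <- integer(0)
    for (a in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[a] <- q[a] + s
      if (q[a] >= 1L && q[a] <= shape[a]) {
        lid <- local_id[q[1L], q[2L], q[3L]]
        if (lid > 0L) out <- c(out, lid)
      }
    }
    out
  }
  fvals <- field[region_idx]
  in_region <- logical(length(region_idx))
  fscore <- rep(-Inf, length(region_idx))   # frontier priority, -Inf = not in it
  seed <- which.max(fvals)
  in_region[seed] <- TRUE
  n_in <- 1L
  for (nb in nbr_of(seed)) if (!in_region[nb]) fscore[nb] <- fvals[nb]
  while (n_in < target_n) {
    nxt <- which.max(fscore)
    if (!is.finite(fscore[nxt])) break      # frontier exhausted
    fscore[nxt] <- -Inf
    in_region[nxt] <- TRUE
    n_in <- n_in + 1L
    for (nb in nbr_of(nxt)) if (!in_region[nb]) fscore[nb] <- fvals[nb]
  }
  region_idx[in_region]
}

# derive a reproducible sub-stream seed (kept well below 2^31)
sub_seed <- function(base, a, b = 0L) {
  (as.numeric(base) * 2654435761 + a * 97561 + b * 7919) %% 2147483629
}

#' Generate one synthetic patient
#'
#' Builds the gland support, the lesion (superlevel set of a 1-3 component
#' Gaussian blob field, thresholded to the target volume drawn log-uniformly
#' from the configured range, restricted to its largest z-connected
#' component), the Gleason-4/5 target sub-region and per-slice delineations,
#' then draws every (observer, image type) mask from the STAPLE generative
#' model, applies boundary perturbation and the per-image-type
#' misregistration shift.
#'
#' @param config A [cohort_config()].
#' @param patient_seed Integer seed for this patient's random streams.
#' @param patient_id Identifier stored in the result.
#' @return A [delineation_set()] whose `truth_params` records the generating
#'   truth: the full lesion mask, per-observer (p, q), boundary offsets and
#'   modality shifts.
#' @export
generate_patient <- function(config, patient_seed, patient_id = "P01") {
  grid <- config$grid
  set.seed(patient_seed %% 2147483629)
  vv <- voxel_volume_mm3(grid)
  centre <- grid$origin_mm + (grid$shape - 1) * grid$spacing_mm / 2

  # gland: jittered ellipsoid, ~43 ml at the default grid
  semi <- c(18, 24, 24) * stats::runif(3, 0.9, 1.1)
  zc <- (axis_coords(grid, 1L) - centre[1L]) / semi[1L]
  yc <- (axis_coords(grid, 2L) - centre[2L]) / semi[2L]
  xc <- (axis_coords(grid, 3L) - centre[3L]) / semi[3L]
  gl <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) <= 1
  gland <- binary_mask(gl, grid)

  # lesion: top-n voxels of a Gaussian blob field inside the gland
  vol_rng <- config$lesion_volume_range_ml
  V <- exp(stats::runif(1, log(vol_rng[1L]), log(vol_rng[2L])))
  n_vox <- max(1L, as.integer(round(V * 1000 / vv)))
  gland_idx <- which(gl)
  if (n_vox > length(gland_idx) %/% 2)
    stop(sprintf("lesion volume %.2f ml infeasible for this grid/gland", V),
         call. = FALSE)
  n_comp <- sample.int(3L, 1L)
  r0 <- (3 * V * 1000 / (4 * pi))^(1 / 3)
  c1 <- centre + stats::runif(3, -0.4, 0.4) * semi
  field <- array(0, dim = grid$shape)
  for (e in seq_len(n_comp)) {
    ce <- if (e == 1L) c1 else c1 + stats::rnorm(3, 0, 0.6 * r0)
    sig <- r0 * stats::runif(3, 0.6, 1.3)
    field <- field + gaussian_field(grid, ce, sig,
                                    if (e == 1L) 1 else stats::runif(1, 0.5, 1))
  }
  ord <- gland_idx[order(field[gland_idx], decreasing = TRUE)[seq_len(n_vox)]]
  lesion_vals <- array(FALSE, dim = grid$shape)
  lesion_vals[ord] <- TRUE

  # keep the largest z-connected component (per-slice footprints merged by
  # consecutive-slice overlap), so the lesion is a single lesion by the
  # pipeline's own definition
  prov <- slices_to_delineations(lesion_vals, lesion_vals, grid, 3L, 3L)
  lab <- merge_lesions_z(prov, grid)
  main_id <- which.max(tabulate(lab$labels[lab$labels > 0L], lab$lesion_count))
  lesion_vals <- lab$labels == main_id
  lesion <- binary_mask(lesion_vals, grid)
  lesion_idx <- which(lesion_vals)

  # Gleason 4/5 target sub-region and per-slice delineations
  frac <- config$gleason4or5_fraction
  if (frac >= 1) {
    g45_idx <- lesion_idx
  } else {
    target_n <- max(1L, as.integer(round(frac * length(lesion_idx))))
    g45_idx <- grow_subregion(field, lesion_idx, target_n, grid$shape)
  }
  g45_vals <- array(FALSE, dim = grid$shape)
  g45_vals[g45_idx] <- TRUE
  pattern_high <- sample(c(4L, 5L), 1L)
  delins <- slices_to_delineations(lesion_vals, g45_vals, grid,
                                   pattern_high, 3L)
  labeling <- merge_lesions_z(delins, grid)
  histo_lesion <- target_lesion_mask(labeling, delins, c(4, 5))

  # observer masks
  shell <- binary_mask(
    expand_margin(lesion, config$fp_shell_mm)$values & !lesion_vals, grid)
  n_types <- length(config$image_types)
  shifts <- matrix(0, nrow = 2L, ncol = n_types,
                   dimnames = list(c("y", "x"), config$image_types))
  for (m in seq_len(n_types)) {
    set.seed(sub_seed(patient_seed, 0L, m))
    shifts[, m] <- stats::rnorm(2, 0, config$misregistration_sd_mm)
  }
  obs_ids <- paste0("obs", seq_len(config$n_observers))
  p_mat <- q_mat <- b_mat <- matrix(
    NA_real_, config$n_observers, n_types,
    dimnames = list(obs_ids, config$image_types))
  masks <- vector("list", config$n_observers)
  names(masks) <- obs_ids
  for (o in seq_len(config$n_observers)) {
    om <- vector("list", n_types)
    names(om) <- config$image_types
    for (m in seq_len(n_types)) {
      ty <- config$image_types[m]
      set.seed(sub_seed(patient_seed, o, m))
      p <- stats::runif(1, config$sensitivity_range[[ty]][1L],
                        config$sensitivity_range[[ty]][2L])
      q <- stats::runif(1, config$specificity_range[[ty]][1L],
                        config$specificity_range[[ty]][2L])
      b <- 0
      if (config$boundary_noise_mm > 0) {
        b <- stats::rnorm(1, 0, config$boundary_noise_mm)
        b <- max(min(b, 2 * config$boundary_noise_mm),
                 -2 * config$boundary_noise_mm)
        b <- round(b / 0.5) * 0.5   # quantized to 0.5 mm
      }
      truth_o <- lesion
      if (b > 0) truth_o <- expand_margin(lesion, b)
      if (b < 0) {
        er <- erode_margin(lesion, -b)
        if (any(er$values)) truth_o <- er   # never erase a tiny lesion
      }
      vals <- array(FALSE, dim = grid$shape)
      tidx <- which(truth_o$values)
      vals[tidx] <- stats::runif(length(tidx)) < p
      sidx <- which(shell$values & !truth_o$values)
      if (length(sidx) > 0L && q < 1)
        vals[sidx] <- stats::runif(length(sidx)) < (1 - q)
      msk <- binary_mask(vals, grid)
      if (any(shifts[, m] != 0)) msk <- shift_mask(msk, shifts[, m])
      om[[ty]] <- msk
      p_mat[o, m] <- p; q_mat[o, m] <- q; b_mat[o, m] <- b
    }
    masks[[o]] <- om
  }
  delineation_set(
    patient_id = patient_id, masks = masks,
    histo_lesion = histo_lesion, histo_support = gland,
    truth_params = list(
      lesion = lesion, lesion_volume_ml = mask_volume_ml(lesion),
      target_volume_ml = mask_volume_ml(histo_lesion),
      drawn_volume_ml = V, sensitivity = p_mat, specificity = q_mat,
      boundary_offset_mm = b_mat, modality_shift_mm = shifts,
      pattern_high = pattern_high, patient_seed = patient_seed))
}

# per-slice delineations from a lesion mask and its Gleason-4/5 sub-mask:
# one high-pattern delineation per slice with 4/5 voxels, one pattern-3
# delineation per slice with remaining lesion voxels
slices_to_delineations <- function(lesion_vals, g45_vals, grid,
                                   pattern_high, pattern_low) {
  out <- list()
  for (s in seq_len(grid$shape[1L])) {
    hi <- g45_vals[s, , ]
    lo <- lesion_vals[s, , ] & !hi
    if (any(hi)) out[[length(out) + 1L]] <-
      slice_delineation(s, hi, pattern_high)
    if (any(lo)) out[[length(out) + 1L]] <-
      slice_delineation(s, lo, pattern_low)
  }
  out
}

#' Generate a synthetic cohort
#'
#' `n_patients` independent patients with per-patient seeds derived
#' deterministically from `config$seed`, so any patient can be regenerated
#' alone.
#'
#' @param config A [cohort_config()].
#' @return Named list of [delineation_set()] objects (`P01`, `P02`, ...).
#' @export
generate_cohort <- function(config) {
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  cohort <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(config, sub_seed(config$seed, i, 0L), ids[i]))
  names(cohort) <- ids
  cohort
}

#' Simulate raters from the STAPLE generative model
#'
#' Each rater's mask keeps every truth voxel with probability `p[j]` and
#' turns on each candidate background voxel with probability `1 - q[j]`. The
#' candidate background is the whole grid outside the truth by default, or a
#' shell of width `shell_mm` around it. Uses the current RNG state.
#'
#' @param truth A [binary_mask()].
#' @param p,q Per-rater sensitivity/specificity vectors (equal length).
#' @param shell_mm Optional false-positive shell width in mm; `NULL` means
#'   the entire background.
#' @return Named list of [binary_mask()] rater decisions.
#' @export
simulate_raters <- function(truth, p, q, shell_mm = NULL) {
  if (length(p) != length(q))
    stop("`p` and `q` must have equal length", call. = FALSE)
  tidx <- which(truth$values)
  bg <- if (is.null(shell_mm)) !truth$values
  else expand_margin(truth, shell_mm)$values & !truth$values
  bidx <- which(bg)
  out <- lapply(seq_along(p), function(j) {
    vals <- array(FALSE, dim = truth$grid$shape)
    vals[tidx] <- stats::runif(length(tidx)) < p[j]
    if (q[j] < 1) vals[bidx] <- stats::runif(length(bidx)) < (1 - q[j])
    binary_mask(vals, truth$grid)
  })
  names(out) <- paste0("rater", seq_along(p))
  out
}
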