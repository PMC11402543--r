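# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use straight loops and direct formula
# transcription, never the package's own code paths.

rand_mask <- function(grid, p = 0.3) {
  binary_mask(array(stats::runif(prod(grid$shape)) < p, dim = grid$shape),
              grid)
}

small_grid <- function(shape = c(4L, 8L, 8L), spacing = c(2.5, 1, 1),
                       origin = c(0, 0, 0)) {
  voxel_grid(shape, spacing, origin)
}

# --- straight-loop binary STAPLE EM reference --------------------------------
staple_reference <- function(masks, params = staple_params()) {
  J <- length(masks)
  V <- prod(masks[[1L]]$grid$shape)
  d <- matrix(0, V, J)
  for (j in seq_len(J)) d[, j] <- as.numeric(masks[[j]]$values)
  gamma <- if (params$prior_mode == "global_fraction") {
    s <- 0
    for (j in seq_len(J)) s <- s + sum(d[, j]) / V
    s / J
  } else params$fixed_prior
  gamma <- min(max(gamma, 1e-6), 1 - 1e-6)
  W <- numeric(V)
  for (i in seq_len(V)) W[i] <- sum(d[i, ]) / J
  p <- q <- numeric(J)
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    sW <- sum(W); sWc <- sum(1 - W)
    for (j in seq_len(J)) {
      p[j] <- sum(W * d[, j]) / sW
      q[j] <- sum((1 - W) * (1 - d[, j])) / sWc
      p[j] <- min(max(p[j], 1e-6), 1 - 1e-6)
      q[j] <- min(max(q[j], 1e-6), 1 - 1e-6)
    }
    Wn <- numeric(V)
    for (i in seq_len(V)) {
      a <- gamma; b <- 1 - gamma
      for (j in seq_len(J)) {
        if (d[i, j] == 1) { a <- a * p[j]; b <- b * (1 - q[j]) }
        else { a <- a * (1 - p[j]); b <- b * q[j] }
      }
      Wn[i] <- a / (a + b)
    }
    delta <- mean(abs(Wn - W))
    W <- Wn
    if (delta < params$tolerance) { converged <- TRUE; break }
  }
  list(W = array(W, dim = masks[[1L]]$grid$shape), p = p, q = q,
       gamma = gamma, converged = converged)
}

# --- direct set-counting metrics ---------------------------------------------
dice_oracle <- function(a, b) {
  ca <- 0L; cb <- 0L; ci <- 0L
  av <- a$values; bv <- b$values
  for (i in seq_along(av)) {
    if (av[i]) ca <- ca + 1L
    if (bv[i]) cb <- cb + 1L
    if (av[i] && bv[i]) ci <- ci + 1L
  }
  2 * ci / (ca + cb)
}

coverage_oracle <- function(gtv, lesion) {
  ci <- 0L; cl <- 0L
  gv <- gtv$values; lv <- lesion$values
  for (i in seq_along(gv)) {
    if (lv[i]) cl <- cl + 1L
    if (gv[i] && lv[i]) ci <- ci + 1L
  }
  ci / cl
}

# --- all-pairs distance margin expansion -------------------------------------
expand_oracle <- function(mask, radius_mm) {
  g <- mask$grid
  fg <- which(mask$values, arr.ind = TRUE)
  out <- array(FALSE, dim = g$shape)
  if (nrow(fg) == 0L) return(binary_mask(out, g))
  fg_mm <- sweep(sweep(fg - 1, 2, g$spacing_mm, `*`), 2, g$origin_mm, `+`)
  all_idx <- which(array(TRUE, dim = g$shape), arr.ind = TRUE)
  all_mm <- sweep(sweep(all_idx - 1, 2, g$spacing_mm, `*`), 2, g$origin_mm, `+`)
  for (v in seq_len(nrow(all_idx))) {
    d2 <- (fg_mm[, 1L] - all_mm[v, 1L])^2 + (fg_mm[, 2L] - all_mm[v, 2L])^2 +
      (fg_mm[, 3L] - all_mm[v, 3L])^2
    if (min(d2) <= radius_mm^2 + 1e-9)
      out[all_idx[v, 1L], all_idx[v, 2L], all_idx[v, 3L]] <- TRUE
  }
  binary_mask(out, g)
}

# --- per-voxel nearest-centre resampling -------------------------------------
resample_oracle <- function(mask, reference) {
  out <- array(FALSE, dim = reference$shape)
  gi <- mask$grid
  in_idx <- which(array(TRUE, dim = gi$shape), arr.ind = TRUE)
  in_mm <- sweep(sweep(in_idx - 1, 2, gi$spacing_mm, `*`), 2, gi$origin_mm, `+`)
  for (k in seq_len(reference$shape[1L]))
    for (j in seq_len(reference$shape[2L]))
      for (i in seq_len(reference$shape[3L])) {
        pt <- reference$origin_mm + (c(k, j, i) - 1) * reference$spacing_mm
        d2 <- (in_mm[, 1L] - pt[1L])^2 + (in_mm[, 2L] - pt[2L])^2 +
          (in_mm[, 3L] - pt[3L])^2
        # ties resolved to the first (lowest-index) voxel, like which.min
        nearest <- in_idx[which.min(d2), ]
        out[k, j, i] <- mask$values[nearest[1L], nearest[2L], nearest[3L]]
      }
  binary_mask(out, reference)
}

# --- graph connected-components oracle for z-merging -------------------------
# partition of delineations: BFS over the pairwise consecutive-slice
# in-plane-overlap graph; returns component id per delineation (arbitrary ids)
merge_oracle_partition <- function(delineations) {
  n <- length(delineations)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    si <- delineations[[i]]$slice_index
    sj <- delineations[[j]]$slice_index
    if (abs(si - sj) == 1L &&
        any(delineations[[i]]$region & delineations[[j]]$region))
      adj[i, j] <- TRUE
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# compare two partitions up to label renaming
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# small delineation-set fixture with random observer masks
rand_dset <- function(grid = small_grid(), n_obs = 3L,
                      types = c("T2w", "DWI", "DCE"), p_fg = 0.3) {
  support <- binary_mask(array(TRUE, dim = grid$shape), grid)
  lesion <- rand_mask(grid, 0.2)
  while (!any(lesion$values)) lesion <- rand_mask(grid, 0.2)
  masks <- lapply(seq_len(n_obs), function(o) {
    om <- lapply(types, function(ty) rand_mask(grid, p_fg))
    names(om) <- types
    om
  })
  names(masks) <- paste0("obs", seq_len(n_obs))
  delineation_set("PX", masks, lesion, support)
}
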