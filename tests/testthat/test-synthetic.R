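small_cfg <- function(seed = 9L, ...) {
  cohort_config(n_patients = 2L, shape = c(10L, 40L, 40L),
                spacing_mm = c(2.5, 1, 1),
                lesion_volume_range_ml = c(0.5, 3), seed = seed, ...)
}

test_that("cohort generation is deterministic and seed-sensitive", {
  cfg <- small_cfg()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$P01$masks$obs1$T2w$values, c2$P01$masks$obs1$T2w$values)
  expect_identical(c1$P02$histo_lesion$values, c2$P02$histo_lesion$values)
  c3 <- generate_cohort(small_cfg(seed = 10L))
  expect_false(identical(c1$P01$masks$obs1$T2w$values,
                         c3$P01$masks$obs1$T2w$values))
})

test_that("a cohort has the configured cardinality and containment structure", {
  cfg <- small_cfg()
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 2L)
  for (d in cohort) {
    expect_length(d$masks, 4L)
    expect_true(all(vapply(d$masks, length, integer(1)) == 4L))
    expect_setequal(image_types(d), c("T2w", "DWI", "DCE", "PSMA-PET"))
    # lesion inside support, target inside full lesion
    expect_false(any(d$histo_lesion$values & !d$histo_support$values))
    expect_false(any(d$histo_lesion$values & !d$truth_params$lesion$values))
  }
})

test_that("lesion volumes respect the configured log-uniform range", {
  cfg <- cohort_config(n_patients = 8L, shape = c(10L, 40L, 40L),
                       spacing_mm = c(2.5, 1, 1),
                       lesion_volume_range_ml = c(0.5, 4), seed = 13L)
  cohort <- generate_cohort(cfg)
  drawn <- vapply(cohort, function(d) d$truth_params$drawn_volume_ml,
                  numeric(1))
  expect_true(all(drawn >= 0.5 & drawn <= 4))
  vols <- vapply(cohort, function(d) d$truth_params$lesion_volume_ml,
                 numeric(1))
  # realized volumes track the drawn ones (voxelization + main component)
  expect_true(all(abs(vols - drawn) / drawn < 0.35))
})

test_that("the noiseless limit reproduces the truth exactly", {
  cfg <- cohort_config(n_patients = 1L, shape = c(10L, 40L, 40L),
                       spacing_mm = c(2.5, 1, 1),
                       lesion_volume_range_ml = c(1, 3), seed = 17L,
                       noiseless = TRUE)
  d <- generate_cohort(cfg)[[1L]]
  truth <- d$truth_params$lesion
  expect_identical(d$histo_lesion$values, truth$values)
  for (obs in observers(d))
    for (ty in image_types(d))
      expect_identical(d$masks[[obs]][[ty]]$values, truth$values)
})

test_that("simulated rater frequencies recover the configured (p, q)", {
  set.seed(19)
  g <- voxel_grid(c(10L, 40L, 40L), c(2.5, 1, 1))
  truth <- empty_mask(g)
  truth$values[3:8, 10:30, 10:30] <- TRUE               # ~2600 voxels
  p <- c(0.8, 0.9, 0.97); q <- c(0.95, 0.97, 0.99)
  raters <- simulate_raters(truth, p, q)
  for (j in seq_along(p)) {
    sens <- sum(raters[[j]]$values & truth$values) / sum(truth$values)
    spec <- sum(!raters[[j]]$values & !truth$values) / sum(!truth$values)
    expect_lt(abs(sens - p[j]), 0.02)
    expect_lt(abs(spec - q[j]), 0.02)
  }
  # false positives confined to the requested shell
  sh <- simulate_raters(truth, 0.9, 0.7, shell_mm = 3)[[1L]]
  fp <- sh$values & !truth$values
  shell <- expand_margin(truth, 3)$values & !truth$values
  expect_true(all(!fp | shell))
  expect_gt(sum(fp), 0)
})

test_that("generated observer masks match their recorded (p, q) empirically", {
  cfg <- cohort_config(n_patients = 2L, shape = c(12L, 48L, 48L),
                       spacing_mm = c(2.5, 1, 1),
                       lesion_volume_range_ml = c(3, 8),
                       boundary_noise_mm = 0, misregistration_sd_mm = 0,
                       gleason4or5_fraction = 1, seed = 23L)
  cohort <- generate_cohort(cfg)
  for (d in cohort) {
    truth <- d$truth_params$lesion
    nt <- sum(truth$values)
    for (obs in observers(d)) for (ty in image_types(d)) {
      m <- d$masks[[obs]][[ty]]
      sens <- sum(m$values & truth$values) / nt
      expect_lt(abs(sens - d$truth_params$sensitivity[obs, ty]), 0.05)
      # false positives only inside the shell, at roughly rate 1 - q
      fp <- m$values & !truth$values
      shell <- expand_margin(truth, cfg$fp_shell_mm)$values & !truth$values
      expect_true(all(!fp | shell))
      expect_lt(abs(sum(fp) / sum(shell) -
                      (1 - d$truth_params$specificity[obs, ty])), 0.05)
    }
  }
})

test_that("infeasible lesion volumes are rejected", {
  cfg <- cohort_config(n_patients = 1L, shape = c(4L, 10L, 10L),
                       spacing_mm = c(2.5, 1, 1),
                       lesion_volume_range_ml = c(50, 50.1), seed = 3L)
  expect_error(generate_patient(cfg, 1L), "infeasible")
})

test_that("cohorts survive a write/read round trip", {
  cfg <- small_cfg()
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back), names(cohort))
  for (pid in names(cohort)) {
    expect_identical(back[[pid]]$histo_lesion$values,
                     cohort[[pid]]$histo_lesion$values)
    expect_identical(back[[pid]]$masks$obs2$DWI$values,
                     cohort[[pid]]$masks$obs2$DWI$values)
  }
  expect_true(file.exists(file.path(dir, "truth.json")))
})
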