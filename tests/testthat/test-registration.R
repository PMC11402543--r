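# a compact two-lobe lesion on a histology-resolution in-plane grid
histo_lesion_fixture <- function() {
  g <- voxel_grid(c(6, 60, 60), c(3, 0.5, 0.5))
  les <- empty_mask(g)
  les$values[2:5, 20:35, 18:40] <- TRUE
  les$values[3:4, 15:38, 15:44] <- TRUE
  les
}

test_that("an exactly representable constructed shift is recovered with DSC 1", {
  les <- histo_lesion_fixture()
  gtv <- shift_mask(les, c(2.0, -1.5))
  al <- optimize_translation(gtv, les, lambda = 0)
  expect_equal(unname(al$translation_mm), c(-2.0, 1.5), tolerance = 1e-9)
  expect_equal(al$dsc_after, 1.0)
  expect_gt(al$dsc_after, al$dsc_before)
})

test_that("aligned inputs and dominant penalties give the zero translation", {
  les <- histo_lesion_fixture()
  al0 <- optimize_translation(les, les, lambda = 0.5)
  expect_equal(unname(al0$translation_mm), c(0, 0))
  expect_equal(al0$dsc_after, 1.0)
  # penalty dwarfing any possible DSC gain pins t at zero
  gtv <- shift_mask(les, c(2.0, -1.5))
  alb <- optimize_translation(gtv, les, lambda = 1e3)
  expect_equal(unname(alb$translation_mm), c(0, 0))
  expect_equal(alb$dsc_after, alb$dsc_before)
  expect_error(optimize_translation(empty_mask(les$grid), les), "empty")
  expect_error(optimize_translation(les, empty_mask(les$grid)), "empty")
  expect_error(optimize_translation(les, les, lambda = -1), "non-negative")
})

test_that("the shift never worsens DSC and distances shrink with lambda", {
  set.seed(71)
  g <- voxel_grid(c(4, 24, 24), c(2.5, 1, 1))
  cases <- lapply(1:3, function(i) {
    les <- empty_mask(g)
    les$values[2:3, 6:16, 6:16] <- TRUE
    noisy <- binary_mask(
      les$values & array(stats::runif(prod(g$shape)) < 0.9, g$shape), g)
    list(gtv = shift_mask(noisy, stats::rnorm(2, 0, 2)), lesion = les)
  })
  lambdas <- c(0, 0.001, 0.01, 0.1, 1)
  for (pen in c("quadratic", "linear")) {
    dists <- sapply(cases, function(cs) {
      sapply(lambdas, function(l) {
        al <- optimize_translation(cs$gtv, cs$lesion, l, penalty = pen)
        expect_gte(al$dsc_after, al$dsc_before - 1e-12)
        sqrt(sum(al$translation_mm^2))
      })
    })
    # per-case mean distance is non-increasing in lambda
    expect_true(all(diff(rowMeans(dists)) <= 1e-12))
  }
})

test_that("volumetric dice under translation interpolates the voxel dice", {
  set.seed(72)
  g <- voxel_grid(c(3, 16, 16), c(2.5, 1, 1))
  a <- rand_mask(g, 0.3); b <- rand_mask(g, 0.3)
  tb <- gtvhisto:::overlap_shift_table(a, b, 5)
  # at voxel-aligned translations it equals the ordinary Dice of the shift
  for (t in list(c(0, 0), c(1, 0), c(-2, 3), c(4, -1))) {
    sh <- shift_mask(a, t)
    expect_equal(gtvhisto:::dice_at_translation(tb, t[1], t[2]), dice(sh, b))
  }
  # halfway between two voxel-aligned shifts it lies between their values
  d0 <- gtvhisto:::dice_at_translation(tb, 0, 0)
  d1 <- gtvhisto:::dice_at_translation(tb, 1, 0)
  dh <- gtvhisto:::dice_at_translation(tb, 0.5, 0)
  expect_gte(dh, min(d0, d1) - 1e-12)
  expect_lte(dh, max(d0, d1) + 1e-12)
})

test_that("penalty calibration handles trivial, boundary and generic targets", {
  les <- histo_lesion_fixture()
  # already aligned, target 0: lambda* = 0, mean 0
  cal0 <- calibrate_penalty_weight(list(A = list(gtv = les, lesion = les)),
                                   target_mean_mm = 0, tolerance_mm = 0.01)
  expect_equal(cal0$lambda_star, 0)
  expect_equal(cal0$mean_distance_mm, 0)
  expect_true(cal0$achieved)
  # target above the unpenalized mean: boundary solution with a warning
  gtv <- shift_mask(les, c(2.0, -1.5))
  expect_warning(
    calb <- calibrate_penalty_weight(list(A = list(gtv = gtv, lesion = les)),
                                     target_mean_mm = 9, tolerance_mm = 0.01),
    "boundary")
  expect_true(calb$boundary)
  expect_equal(calb$lambda_star, 0)
  # generic target between 0 and the unpenalized optimum is reachable
  cal <- calibrate_penalty_weight(list(A = list(gtv = gtv, lesion = les)),
                                  target_mean_mm = 1.2, tolerance_mm = 0.05)
  expect_lte(abs(cal$mean_distance_mm - 1.2), 0.05)
  expect_true(cal$achieved)
})

test_that("calibrated shifts propagate into the overlap records", {
  set.seed(73)
  cfg <- cohort_config(n_patients = 2L, shape = c(8L, 32L, 32L),
                       spacing_mm = c(2.5, 1, 1),
                       lesion_volume_range_ml = c(1, 3),
                       misregistration_sd_mm = 2, boundary_noise_mm = 0,
                       seed = 5L)
  cohort <- generate_cohort(cfg)
  cases <- lapply(cohort, function(d)
    list(gtv = calibration_gtv(d), lesion = d$histo_lesion))
  cal <- calibrate_penalty_weight(cases, target_mean_mm = 1,
                                  tolerance_mm = 0.5, search_radius_mm = 6)
  rec <- apply_calibrated_shift(cohort, cal, margins_mm = 0)
  expect_equal(nrow(rec), 2L * 7L)
  # zero translations reproduce the unshifted evaluation
  cal$per_patient <- lapply(cal$per_patient, function(r) {
    r$translation_mm <- c(y = 0, x = 0); r })
  rec0 <- apply_calibrated_shift(cohort, cal, margins_mm = 0)
  plain <- evaluate_cohort(cohort, margins_mm = 0, sources = "staple")
  expect_equal(rec0$dsc, plain$dsc)
  expect_equal(rec0$coverage, plain$coverage)
  cal$per_patient[["P02"]] <- NULL
  expect_error(apply_calibrated_shift(cohort, cal), "no calibrated translation")
})
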