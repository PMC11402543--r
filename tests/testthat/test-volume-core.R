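test_that("grid and mask constructors validate their invariants", {
  expect_error(voxel_grid(c(0, 4, 4), c(1, 1, 1)), "shape")
  expect_error(voxel_grid(c(4, 4, 4), c(0, 1, 1)), "spacing")
  g <- voxel_grid(c(4, 8, 8), c(2.5, 1, 1), c(-1, 0, 3))
  expect_error(binary_mask(array(TRUE, dim = c(4, 8, 7)), g), "dimensions")
  m <- binary_mask(array(c(0, 1, 2, 0), dim = c(4, 8, 8))[, , ], g)
  expect_true(is.logical(m$values))
  expect_equal(voxel_volume_mm3(g), 2.5)
})

test_that("mask volume is count times voxel volume", {
  g <- voxel_grid(c(4, 10, 10), c(5, 1, 1))
  m <- empty_mask(g)
  expect_equal(mask_volume_ml(m), 0)
  m$values[1, , ] <- TRUE          # 100 voxels x 5 mm^3
  expect_equal(mask_volume_ml(m), 0.5)
  g1 <- voxel_grid(c(1, 1, 1), c(1, 1, 1))
  m1 <- binary_mask(array(TRUE, dim = c(1, 1, 1)), g1)
  expect_equal(mask_volume_ml(m1), 0.001)
})

test_that("NIfTI and NRRD round trips preserve values and geometry", {
  set.seed(11)
  g <- voxel_grid(c(4, 8, 8), c(5, 0.5, 0.5), c(-3.25, 4.5, 10))
  for (ext in c(".nii.gz", ".nii", ".nrrd")) {
    m <- rand_mask(g)
    f <- withr::local_tempfile(fileext = ext)
    write_mask(m, f)
    m2 <- read_mask(f)
    expect_identical(m2$values, m$values)
    expect_true(grid_equal(m2$grid, g, tol = 1e-6))
  }
  # empty mask round trip
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_mask(empty_mask(g), f)
  expect_equal(sum(read_mask(f)$values), 0)
})

test_that("gzip-encoded NRRD payloads are readable", {
  set.seed(12)
  g <- voxel_grid(c(3, 6, 6), c(2, 1, 1))
  m <- rand_mask(g)
  raw_f <- withr::local_tempfile(fileext = ".nrrd")
  write_mask(m, raw_f)
  # recompress the payload by hand
  bytes <- readBin(raw_f, "raw", n = file.size(raw_f))
  nl <- which(bytes == as.raw(10L))
  hdr_end <- nl[which(diff(nl) == 1L)[1L] + 1L]
  hdr <- rawToChar(bytes[seq_len(hdr_end)])
  hdr <- sub("encoding: raw", "encoding: gzip", hdr)
  gz_f <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(gz_f, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(memCompress(bytes[(hdr_end + 1L):length(bytes)], "gzip"), con)
  close(con)
  m2 <- read_mask(gz_f)
  expect_identical(m2$values, m$values)
})

test_that("read_mask binarizes multi-valued volumes and reports format errors", {
  # values {0, 1, 2}: foreground = all non-zero voxels
  arr <- array(0L, dim = c(5, 5, 3))
  arr[1, 1, 1] <- 1L; arr[2, 2, 2] <- 2L; arr[3, 3, 3] <- 2L
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), f)
  m <- read_mask(f)
  expect_equal(sum(m$values), sum(arr != 0))

  expect_error(read_mask(file.path(tempdir(), "nope.nii.gz")), "not found")
  # 4D payload is rejected
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0L, dim = c(4, 4, 2, 2))), f4)
  expect_error(read_mask(f4), "3D")
  # NRRD header lacking spacing information names the missing field
  fh <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "encoding: raw", ""), fh, sep = "\n")
  con <- file(fh, "ab"); writeBin(as.raw(rep(1L, 8)), con); close(con)
  expect_error(read_mask(fh), "space directions")
})

test_that("mask_union is commutative, associative, idempotent and exact", {
  set.seed(21)
  g <- small_grid()
  a <- rand_mask(g); b <- rand_mask(g); c0 <- rand_mask(g)
  expect_identical(mask_union(list(a, a))$values, a$values)
  expect_identical(mask_union(list(a, b))$values, mask_union(list(b, a))$values)
  expect_identical(mask_union(list(mask_union(list(a, b)), c0))$values,
                   mask_union(list(a, mask_union(list(b, c0))))$values)
  expect_identical(mask_union(list(a, empty_mask(g)))$values, a$values)
  # disjoint counts add
  d1 <- empty_mask(g); d1$values[1, 1, 1:3] <- TRUE
  d2 <- empty_mask(g); d2$values[2, 2, 1:5] <- TRUE
  expect_equal(sum(mask_union(list(d1, d2))$values), 8)
  expect_error(mask_union(list()), "non-empty")
  g2 <- voxel_grid(c(4, 8, 8), c(1, 1, 1))
  expect_error(mask_union(list(a, rand_mask(g2))), "different voxel grids")
})

test_that("crop_to_support is an intersection with the expected bounds", {
  set.seed(22)
  g <- small_grid()
  m <- rand_mask(g); s <- rand_mask(g, 0.5)
  cr <- crop_to_support(m, s)
  expect_true(all(!cr$values | m$values))
  expect_true(all(!cr$values | s$values))
  expect_lte(mask_volume_ml(cr), min(mask_volume_ml(m), mask_volume_ml(s)))
  expect_identical(crop_to_support(m, binary_mask(array(TRUE, g$shape), g))$values,
                   m$values)
  expect_equal(sum(crop_to_support(m, empty_mask(g))$values), 0)
})

test_that("nearest-neighbour resampling matches the per-voxel oracle", {
  set.seed(23)
  # identity on the own grid
  g <- voxel_grid(c(3, 6, 6), c(2.5, 1, 1), c(0.5, -1, 2))
  m <- rand_mask(g)
  expect_identical(resample_nearest(m, g)$values, m$values)
  # full-foreground mask onto an interior grid stays full
  full <- binary_mask(array(TRUE, g$shape), g)
  inner <- voxel_grid(c(2, 4, 4), c(2.5, 1, 1), c(1, 0, 3))
  expect_true(all(resample_nearest(full, inner)$values))
  # random anisotropic-to-fine resampling vs brute force
  for (rep in 1:5) {
    src <- voxel_grid(c(3, 5, 4), c(3, 1.5, 2), c(-1, 0.5, 0))
    dst <- voxel_grid(c(5, 8, 7), c(1.1, 0.7, 0.9), c(-2, 0, -0.5))
    m <- rand_mask(src, 0.4)
    expect_identical(resample_nearest(m, dst)$values,
                     resample_oracle(m, dst)$values)
  }
  # a single voxel onto a 2x finer grid: exactly the nearest-centre voxels
  src <- voxel_grid(c(1, 4, 4), c(1, 2, 2))
  one <- empty_mask(src); one$values[1, 2, 3] <- TRUE
  fine <- voxel_grid(c(1, 8, 8), c(1, 1, 1), c(0, -0.5, -0.5))
  expect_identical(resample_nearest(one, fine)$values,
                   resample_oracle(one, fine)$values)
})

test_that("shift_mask moves content by the nearest voxel displacement", {
  g <- voxel_grid(c(2, 6, 6), c(2.5, 1, 1))
  m <- empty_mask(g); m$values[1, 3, 3] <- TRUE
  s <- shift_mask(m, c(2, -1))
  expect_true(s$values[1, 5, 2])
  expect_equal(sum(s$values), 1)
  # content shifted off the grid is lost
  expect_equal(sum(shift_mask(m, c(10, 0))$values), 0)
  # zero shift is the identity
  expect_identical(shift_mask(m, c(0, 0))$values, m$values)
})
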