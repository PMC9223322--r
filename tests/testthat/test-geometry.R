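test_that("voxel geometry and orientation field validate their invariants", {
  expect_error(voxel_geometry(array(TRUE, c(2, 2)), 1), "3-d")
  expect_error(voxel_geometry(array(TRUE, c(2, 2, 2)), spacing = 0), "positive")

  g <- voxel_geometry(array(TRUE, c(3, 2, 2)), spacing = 300)
  expect_equal(n_occupied(g), 12)

  # zero vector at an occupied voxel is reported with its index
  v <- array(0, c(3, 2, 2, 3)); v[, , , 1] <- 1
  v[2, 1, 1, ] <- 0
  expect_error(orientation_field(v, g), "2,1,1")

  # non-unit vectors are renormalized; sign is canonical (axial data)
  v <- array(0, c(3, 2, 2, 3)); v[, , , 1] <- -3
  f <- orientation_field(v, g)
  expect_true(all(f$vectors[, , , 1] == 1))

  # vectors outside the mask are discarded
  m <- array(TRUE, c(3, 2, 2)); m[1, 1, 1] <- FALSE
  g2 <- voxel_geometry(m)
  f2 <- orientation_field(v, g2)
  expect_true(is.na(f2$vectors[1, 1, 1, 1]))
})

test_that("geometry containers round-trip bit-exactly (NIfTI and native)", {
  fx <- make_fixture(fixture_spec("slab", dims = c(10, 8, 3), thickness = 3,
                                  fibre_angle = 0.5))
  td <- withr::local_tempdir()
  for (fmt in c("nifti", "rds")) {
    write_geometry(fx$geometry, fx$field, file.path(td, fmt), fmt)
    rt <- read_geometry(file.path(td, fmt), fmt)
    expect_identical(rt$geometry$mask, fx$geometry$mask)
    expect_identical(rt$geometry$spacing, fx$geometry$spacing)
    expect_identical(rt$field$vectors, fx$field$vectors)
  }
  # mask-only file: usable by the null model, field absent
  write_geometry(fx$geometry, NULL, file.path(td, "m"), "nifti")
  rt <- read_geometry(file.path(td, "m"), "nifti")
  expect_null(rt$field)
  expect_identical(rt$geometry$mask, fx$geometry$mask)
})

test_that("coarse graining averages axial orientations via the structure tensor", {
  fx <- make_fixture(fixture_spec("slab", dims = c(8, 6, 4), thickness = 4))

  # factor 1 is the identity
  out1 <- coarse_grain_field(fx$geometry, fx$field, 1)
  expect_identical(out1$geometry, fx$geometry)
  expect_identical(out1$field, fx$field)

  # uniform field stays uniform
  out2 <- coarse_grain_field(fx$geometry, fx$field, 2)
  expect_equal(out2$geometry$dim, c(4, 3, 2))
  expect_equal(n_occupied(out2$geometry), 24)
  expect_equal(out2$geometry$spacing, 2)
  occ <- out2$geometry$mask
  expect_true(all(abs(out2$field$vectors[, , , 1][occ]) == 1))

  # antiparallel vectors reinforce instead of cancelling: the structure
  # tensor of half +x / half -x has principal eigenvector +/-(1,0,0)
  m <- array(TRUE, c(2, 2, 2))
  v <- array(0, c(2, 2, 2, 3)); v[, , , 1] <- rep(c(1, -1), 4)
  g <- voxel_geometry(m)
  cg <- coarse_grain_field(g, orientation_field(v, g), 2)
  # hand-computed tensor: mean of v v^T = diag(1, 0, 0)
  Tm <- matrix(0, 3, 3)
  for (s in rep(c(1, -1), 4)) Tm <- Tm + c(s, 0, 0) %o% c(s, 0, 0) / 8
  ev <- eigen(Tm, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(cg$field$vectors[1, 1, 1, ]), abs(ev))
  expect_equal(abs(cg$field$vectors[1, 1, 1, 1]), 1)
})

test_that("structure-tensor averaging is invariant to axial sign flips", {
  set.seed(7)
  g <- voxel_geometry(array(TRUE, c(4, 4, 4)))
  raw <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  f1 <- orientation_field(raw, g)
  flip <- array(sample(c(-1, 1), 64, replace = TRUE), c(4, 4, 4))
  raw2 <- raw
  for (c_ in 1:3) raw2[, , , c_] <- raw2[, , , c_] * flip
  f2 <- orientation_field(raw2, g)
  cg1 <- coarse_grain_field(g, f1, 2)$field
  cg2 <- coarse_grain_field(g, f2, 2)$field
  # orientations agree up to sign; canonical axial form makes them identical
  expect_equal(cg1$vectors, cg2$vectors)
})

test_that("coarse occupancy keeps blocks with at least half occupied children", {
  m <- array(FALSE, c(4, 2, 2))
  m[1:2, , ] <- TRUE            # block 1: fully occupied
  m[3, 1, 1] <- TRUE            # block 2: 1 of 8 children
  g <- voxel_geometry(m)
  out <- coarse_grain_field(g, NULL, 2)
  expect_equal(as.vector(out$geometry$mask), c(TRUE, FALSE))

  # tie (exactly half) counts as occupied
  m2 <- array(FALSE, c(2, 2, 2)); m2[1, , ] <- TRUE
  out2 <- coarse_grain_field(voxel_geometry(m2), NULL, 2)
  expect_true(out2$geometry$mask[1, 1, 1])

  expect_error(coarse_grain_field(g, NULL, 0), "positive integer")
})
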