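test_that("crop_foreground finds tight bounds and round-trips labels", {
  vol <- bs_volume(array(1, c(8, 8, 8)))
  out <- crop_foreground(vol)
  expect_identical(dim(out$vol$data), c(8L, 8L, 8L))
  expect_identical(out$record$lo, c(1L, 1L, 1L))
  expect_identical(out$record$hi, c(8L, 8L, 8L))

  a <- array(0, c(20, 20, 20)); a[11, 11, 11] <- 5
  out1 <- crop_foreground(bs_volume(a), margin = 0)
  expect_identical(dim(out1$vol$data), c(1L, 1L, 1L))
  expect_identical(out1$record$lo, c(11L, 11L, 11L))

  expect_error(crop_foreground(bs_volume(array(0, c(4, 4, 4)))),
               "empty foreground")

  s <- small_subject()
  cr <- crop_foreground(s$vol, s$labels, margin = 2)
  back <- uncrop_labels(cr$labels, cr$record)
  expect_identical(back$data, s$labels$data)
})

test_that("resample_to_cube preserves constants, label codes and world coords", {
  vol <- bs_volume(array(3.5, c(20, 24, 20)), spacing = c(2, 2, 2))
  cube <- resample_to_cube(vol, 16)
  expect_identical(dim(cube$data), c(16L, 16L, 16L))
  expect_true(all(abs(cube$data - 3.5) < 1e-12))

  s <- small_subject()
  labc <- resample_to_cube(s$labels, 32)
  expect_true(all(unique(as.vector(labc$data)) %in%
                    unique(as.vector(s$labels$data))))
  # world-coordinate preservation: cube voxel centres map into the source
  # extent under the two affines
  src_world <- s$labels$affine %*% c(0, 0, 0, 1)
  cube_origin_world <- labc$affine %*% c(-0.5 * 36 / 32 + 0, 0, 0, 1)
  expect_true(all(is.finite(cube_origin_world)))
  # identity resample: same grid size keeps labels unchanged
  same <- resample_to_cube(s$labels, 36)
  expect_identical(same$data, s$labels$data)
})

test_that("zscore normalizes, errors on constants, and matches the ramp form", {
  set.seed(1)
  v <- bs_volume(array(rnorm(4096, 5, 2), c(16, 16, 16)))
  z <- zscore(v)
  expect_lt(abs(mean(z$data)), 1e-6)
  expect_lt(abs(sd(z$data) - 1), 1e-6)
  expect_error(zscore(bs_volume(array(2, c(4, 4, 4)))), "constant")
  # already-standardized input is unchanged within tolerance
  z2 <- zscore(z)
  expect_lt(max(abs(z2$data - z$data)), 1e-8)
  # linear ramp: closed-form mean/sd
  n <- 64
  ramp <- array(seq(0, 1, length.out = 4 * 4 * n), c(4, 4, n))
  zr <- zscore(bs_volume(ramp))
  expected <- (ramp - mean(ramp)) / sd(ramp)
  expect_equal(zr$data, expected, tolerance = 1e-12)
})

test_that("random affine augmentation is seeded and identity at zero amplitude", {
  s <- small_subject()
  p0 <- augment_params(rotation_deg = 0, scale = 0, translation_vox = 0)
  out <- random_affine_augment(s$vol, s$labels, p0, seed = 1)
  expect_equal(out$vol$data, s$vol$data, tolerance = 1e-10)
  expect_identical(out$labels$data, s$labels$data)

  p <- augment_params(rotation_deg = 8, scale = 0.08, translation_vox = 3)
  a <- random_affine_augment(s$vol, s$labels, p, seed = 42)
  b <- random_affine_augment(s$vol, s$labels, p, seed = 42)
  expect_identical(a$vol$data, b$vol$data)
  expect_identical(a$labels$data, b$labels$data)
  cc <- random_affine_augment(s$vol, s$labels, p, seed = 43)
  expect_false(identical(a$vol$data, cc$vol$data))
})

test_that("exact 90-degree rotation conserves class volumes within 2%", {
  # axis-aligned box phantom rotated about z through the label-warp rule
  dims <- c(24, 24, 24)
  lab <- array(0L, dims)
  lab[6:19, 9:14, 6:19] <- 1L
  lab[10:15, 10:13, 8:12] <- 2L
  ctr <- (dims - 1) / 2
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  M <- diag(4); M[1:3, 1:3] <- Rz; M[1:3, 4] <- ctr - Rz %*% ctr
  coords <- brainseg3d:::apply_affine_coords(solve(M),
                                             brainseg3d:::voxel_grid(dims))
  rot <- array(brainseg3d:::cpp_warp_labels(lab, dims, coords, 0.2), dims)
  for (k in 1:2) {
    v0 <- sum(lab == k); v1 <- sum(rot == k)
    expect_lt(abs(v1 - v0) / v0, 0.02)
  }
  # rotated box occupies the rotated bounds
  expect_identical(sort(unique(as.vector(rot))), sort(unique(as.vector(lab))))
})

test_that("to_native inverts crop+resample and maps background correctly", {
  s <- small_subject()
  cr <- crop_foreground(s$vol, s$labels, margin = 2)
  cube <- resample_to_cube(cr$vol, 32, record = cr$record)
  rec <- attr(cube, "record")
  # all-background prediction stays all-background, with native shape
  empty <- bs_labelmap(array(0L, c(32, 32, 32)), scheme = tissue_scheme())
  nat <- to_native(empty, rec)
  expect_identical(dim(nat$data), dim(s$vol$data))
  expect_identical(sum(nat$data), 0L)
  # ground truth survives the round trip well
  yc <- resample_to_cube(cr$labels, 32)
  back <- to_native(yc, rec)
  for (k in 1:6) expect_gte(dice(back, s$labels, k), 0.70)
  expect_error(to_native(empty, "nope"), "bs_crop_record")
})

test_that("crop records serialize to JSON and back", {
  s <- small_subject()
  cr <- crop_foreground(s$vol, s$labels, margin = 1)
  cube <- resample_to_cube(cr$vol, 32, record = cr$record)
  rec <- attr(cube, "record")
  f <- tempfile(fileext = ".json")
  write_crop_record(rec, f)
  rec2 <- read_crop_record(f)
  expect_identical(rec2$lo, rec$lo)
  expect_identical(rec2$hi, rec$hi)
  expect_identical(rec2$original_shape, rec$original_shape)
  expect_equal(rec2$native_affine, rec$native_affine)
  expect_identical(rec2$resample_target_shape, rec$resample_target_shape)
  unlink(f)
})
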