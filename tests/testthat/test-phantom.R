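test_that("template contains all six tissue classes with WM largest", {
  tpl <- small_template()
  codes <- sort(unique(as.vector(tpl$labels$data)))
  expect_identical(codes, 0:6)
  counts <- table(tpl$labels$data)[-1]   # brain classes only
  expect_identical(names(which.max(counts)), "3")
  expect_gt(min(counts), 0)
  # geometry agreement between image and labels
  expect_identical(tpl$vol$affine, tpl$labels$affine)
  expect_identical(dim(tpl$vol$data), dim(tpl$labels$data))
})

test_that("template generation is deterministic and rejects tiny grids", {
  s <- small_spec()
  t1 <- make_template(s)
  t2 <- make_template(s)
  expect_identical(t1$vol$data, t2$vol$data)
  expect_identical(t1$labels$data, t2$labels$data)
  expect_error(make_template(phantom_spec(grid_shape = c(16, 64, 64))),
               "grid too small")
})

test_that("subjects are deterministic given seed and carry valid lesions", {
  tpl <- small_template()
  spec <- small_spec()
  a <- sample_subject(tpl, spec, seed = 11)
  b <- sample_subject(tpl, spec, seed = 11)
  expect_identical(a$vol$data, b$vol$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$lesions$wm, b$lesions$wm)
  # default lesions are WM lesions, strictly inside WM ground truth
  expect_gt(sum(a$lesions$wm), 0)
  expect_true(all(a$labels$data[a$lesions$wm] == 3L))
  expect_identical(sum(a$lesions$gm), 0L)
  expect_identical(sort(unique(as.vector(a$labels$data))), 0:6)
})

test_that("lesion_count = 0 gives empty masks", {
  spec <- small_spec(lesion_count = 0)
  s <- sample_subject(make_template(spec), spec, seed = 3)
  expect_identical(sum(s$lesions$wm) + sum(s$lesions$gm), 0L)
})

test_that("hypointense WM lesions are darker than non-lesional WM", {
  spec <- small_spec(noise_sd = 0, bias_amplitude = 0)
  s <- sample_subject(make_template(spec), spec, seed = 5)
  wm_normal <- s$labels$data == 3 & !s$lesions$wm
  expect_lt(mean(s$vol$data[s$lesions$wm]), mean(s$vol$data[wm_normal]))
})

test_that("contrast_scale = 0 makes deep gray isointense to white matter", {
  spec <- small_spec(contrast_scale = 0, noise_sd = 0, bias_amplitude = 0,
                     lesion_count = 0)
  s <- sample_subject(make_template(spec), spec, seed = 5)
  m_dgm <- mean(s$vol$data[s$labels$data == 4])
  m_wm <- mean(s$vol$data[s$labels$data == 3])
  expect_lt(abs(m_dgm - m_wm), 3)   # boundary smoothing only
})

test_that("GM lesions land in gray matter", {
  # gray matter structures are thin/small, so this needs the full-size grid
  spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = c(3, 3, 3),
                       lesion_tissue = "GM", lesion_count = 2,
                       lesion_radius_range_mm = c(4, 6))
  s <- sample_subject(make_template(spec), spec, seed = 9)
  expect_gt(sum(s$lesions$gm), 0)
  expect_true(all(s$labels$data[s$lesions$gm] %in% c(2L, 4L)))
})

test_that("subject warp composed with its inverse recovers template labels", {
  spec <- phantom_spec()                  # default 64^3 scale
  tpl <- make_template(spec)
  s <- sample_subject(tpl, spec, seed = 7)
  dims <- dim(s$labels$data)
  dinv <- invert_displacement(s$warp)
  g <- brainseg3d:::voxel_grid(dims)
  cc <- cbind(g[, 1] + as.vector(dinv$x), g[, 2] + as.vector(dinv$y),
              g[, 3] + as.vector(dinv$z))
  rec <- array(brainseg3d:::cpp_warp_labels(s$labels$data, dims, cc, 0.2),
               dim = dims)
  for (k in 1:6)
    expect_gte(dice(rec, tpl$labels$data, k), 0.95)
})

test_that("make_cohort writes a seeded, disjoint split and manifest", {
  spec <- small_spec()
  d1 <- file.path(tempdir(), "cohortA")
  unlink(d1, recursive = TRUE)
  res <- make_cohort(spec, n = 10, seed = 3, dir = d1,
                     fractions = c(0.8, 0.1, 0.1))
  expect_equal(nrow(res$manifest), 10)
  expect_equal(as.integer(table(res$manifest$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  expect_true(all(file.exists(res$manifest$t1)))
  expect_error(make_cohort(spec, n = 2, seed = 3, dir = d1),
               "overwrite")
  # identical seed reproduces the manifest
  d2 <- file.path(tempdir(), "cohortB")
  unlink(d2, recursive = TRUE)
  res2 <- make_cohort(spec, n = 10, seed = 3, dir = d2,
                      fractions = c(0.8, 0.1, 0.1))
  expect_identical(res$manifest$split, res2$manifest$split)
  expect_identical(res$manifest$n_wm_lesion_vox, res2$manifest$n_wm_lesion_vox)
  # NIfTI round trip preserves labels and grid
  lab <- read_labelmap(res$manifest$labels[1])
  expect_identical(dim(lab$data), spec$grid_shape)
  expect_true(all(lab$data %in% 0:6))
  unlink(c(d1, d2), recursive = TRUE)
})
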