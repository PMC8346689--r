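test_that("dice matches confusion-count cases and conventions", {
  a <- array(0L, c(2, 2, 1)); a[1, 1, 1] <- 1L; a[2, 1, 1] <- 1L; a[1, 2, 1] <- 1L
  b <- array(0L, c(2, 2, 1)); b[1, 1, 1] <- 1L; b[2, 1, 1] <- 1L; b[2, 2, 1] <- 1L
  # TP=2, FP=1, FN=1 -> 4/6
  expect_equal(dice(a, b, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(dice(a, a, 1), 1.0)
  expect_equal(dice(a, 1L - a, 1), 0.0)
  expect_equal(dice(a, a, 5), 1.0)     # both empty -> 1 by convention
})

test_that("volume similarity is location-blind and matches its formula", {
  x <- array(0L, c(4, 4, 1)); x[1:3, 1, 1] <- 1L           # V = 3
  y <- array(0L, c(4, 4, 1)); y[4, 4, 1] <- 1L             # V = 1, disjoint
  expect_equal(volume_similarity(x, y, 1), 0.5)            # 1 - 2/4
  # equal volumes, even if disjoint -> 1
  y2 <- array(0L, c(4, 4, 1)); y2[1:3, 4, 1] <- 1L
  expect_equal(volume_similarity(x, y2, 1), 1.0)
  expect_equal(volume_similarity(x, array(0L, c(4, 4, 1)), 1), 0.0)
  # invariant under spatial permutation of the prediction
  set.seed(1)
  xp <- array(sample(as.vector(x)), dim(x))
  expect_equal(volume_similarity(xp, y, 1), volume_similarity(x, y, 1))
})

test_that("hd95 handles exact cases and anisotropic spacing", {
  p <- array(0L, c(8, 8, 8)); p[2, 2, 2] <- 1L
  t <- array(0L, c(8, 8, 8)); t[5, 2, 2] <- 1L
  expect_equal(hd95(p, t, 1, spacing = c(1, 1, 1)), 3.0)
  expect_equal(hd95(p, t, 1, spacing = c(2, 1, 1)), 6.0)
  expect_equal(hd95(p, p, 1, spacing = c(1, 1, 1)), 0.0)
  expect_true(is.nan(hd95(p, array(0L, c(8, 8, 8)), 1, spacing = c(1, 1, 1))))
  # 20 pred voxels: 19 at distance 0, 1 at distance 10 (95th percentile
  # interpolates between the order statistics) vs brute-force oracle
  p2 <- array(0L, c(30, 4, 4)); t2 <- p2
  p2[1:19, 1, 1] <- 1L; p2[29, 1, 1] <- 1L
  t2[1:19, 1, 1] <- 1L
  expect_equal(hd95(p2, t2, 1, spacing = c(1, 1, 1)),
               oracle_hd95(p2, t2, 1, c(1, 1, 1)), tolerance = 1e-9)
})

test_that("intra-lesion accuracy follows the label rules", {
  pred <- array(3L, c(4, 4, 4))
  wm <- array(FALSE, c(4, 4, 4)); wm[1:2, 1, 1] <- TRUE
  acc <- intra_lesion_accuracy(pred, wm_lesion = wm)
  expect_equal(acc$acc_wm, 1.0)
  expect_true(is.na(acc$acc_gm))
  # gm mask of 4 voxels predicted (2, 4, 3, 0) -> 0.5
  pred2 <- array(0L, c(4, 4, 4))
  pred2[1, 1, 1] <- 2L; pred2[2, 1, 1] <- 4L; pred2[3, 1, 1] <- 3L
  gm <- array(FALSE, c(4, 4, 4)); gm[1:4, 1, 1] <- TRUE
  expect_equal(intra_lesion_accuracy(pred2, gm_lesion = gm)$acc_gm, 0.5)
  # all-background prediction -> 0
  expect_equal(intra_lesion_accuracy(array(0L, c(4, 4, 4)),
                                     gm_lesion = gm, wm_lesion = wm)$acc_wm, 0)
})

test_that("z comparison matches its closed form and is antisymmetric", {
  z <- z_from_summary(0.86, 0.05, 52, 0.82, 0.06, 52)
  expect_equal(z$z, 0.04 / sqrt(0.05^2 / 52 + 0.06^2 / 52), tolerance = 1e-12)
  expect_true(z$significant)
  expect_identical(z$direction, "group1_higher")

  set.seed(2)
  s1 <- rnorm(20); s2 <- rnorm(20, 1)
  za <- z_compare(s1, s2); zb <- z_compare(s2, s1)
  expect_equal(za$z, -zb$z, tolerance = 1e-12)
  expect_equal(z_compare(s1, s1)$z, 0)
  expect_false(z_compare(s1, s1)$significant)
  # degenerate variance conventions
  expect_equal(z_from_summary(1, 0, 5, 1, 0, 5)$z, 0)
  expect_identical(z_from_summary(2, 0, 5, 1, 0, 5)$z, Inf)
  expect_true(z_from_summary(2, 0, 5, 1, 0, 5)$significant)
  expect_error(z_compare(1, c(1, 2)), "n >= 2")
})

test_that("evaluate_cohort aggregates per-tissue and overall", {
  s <- small_subject()
  rep1 <- evaluate_cohort(list(s$labels), list(s$labels),
                          lesion_masks = list(s$lesions))
  expect_equal(nrow(rep1$per_subject), 6)
  expect_true(all(rep1$per_subject$dice == 1))
  expect_true(all(rep1$per_subject$vs == 1))
  expect_true(all(rep1$per_subject$hd95_mm == 0))
  expect_equal(rep1$overall$dice_mean, 1)
  expect_equal(rep1$overall$dice_sd, 0)
  expect_identical(sort(rep1$per_subject$class),
                   sort(names(tissue_scheme()[-1])))
  # perfect prediction classifies lesions by their underlying tissue
  expect_equal(rep1$intra_lesion$wm$mean, 1)
  expect_error(evaluate_cohort(list(s$labels), list()), "matching")
})

test_that("metrics are invariant under consistent class relabeling", {
  set.seed(3)
  p <- random_labels(c(6, 6, 6), 0:3)
  t <- random_labels(c(6, 6, 6), 0:3)
  # relabel 1 -> 11, 2 -> 12, 3 -> 13 in both
  lut <- c(0L, 11L, 12L, 13L)
  p2 <- array(lut[p + 1L], dim(p)); t2 <- array(lut[t + 1L], dim(t))
  for (k in 1:3) {
    expect_equal(dice(p, t, k), dice(p2, t2, k + 10L))
    expect_equal(volume_similarity(p, t, k), volume_similarity(p2, t2, k + 10L))
    expect_equal(hd95(p, t, k, spacing = c(1, 1, 1)),
                 hd95(p2, t2, k + 10L, spacing = c(1, 1, 1)))
  }
})

test_that("external labels harmonize to the internal scheme", {
  ext <- array(0L, c(4, 4, 4))
  ext[1, , ] <- 1L   # CSF
  ext[2, , ] <- 6L   # ventricles
  ext[3, , ] <- 4L   # WMH
  ext[4, 1, ] <- 2L  # basal ganglia
  ext[4, 2, ] <- 5L  # cortical GM
  ext[4, 3, ] <- 9L  # infarction
  h <- harmonize_external_labels(bs_labelmap(ext, scheme = external_scheme()))
  expect_true(all(h$data[1, , ] == 1L))
  expect_true(all(h$data[2, , ] == 1L))     # condensed with CSF
  expect_true(all(h$data[3, , ] == 3L))     # WMH -> WM
  expect_true(all(h$data[4, 1, ] == 4L))
  expect_true(all(h$data[4, 2, ] == 2L))
  expect_true(all(h$data[4, 3, ] == 255L))  # excluded
  em <- excluded_mask(h)
  expect_identical(sum(em), sum(ext == 9L))
  # excluded voxels leave the dice denominators
  pred <- h$data; pred[em] <- 3L
  expect_equal(dice(pred, h, 3, ignore = em), 1.0)
  expect_error(harmonize_external_labels(array(42L, c(2, 2, 2))), "unknown")
})
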