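test_that("network configuration enforces the mode invariants", {
  expect_error(net_config(out_channels = 6, final_activation = "softmax"),
               "sigmoid")
  expect_error(net_config(out_channels = 7, final_activation = "sigmoid"),
               "softmax")
  expect_error(net_config(out_channels = 1, final_activation = "softmax"),
               "sigmoid")
  expect_error(net_config(input_shape = c(24, 24, 24)), "divisible")
  cfg <- net_config(in_channels = 2, out_channels = 6, base_filters = 4,
                    input_shape = c(32, 32, 32))
  expect_s3_class(cfg, "bs_net_config")
})

tiny_net <- function(out_channels = 6, in_channels = 1, bf = 2,
                     act = if (out_channels == 7) "softmax" else "sigmoid") {
  build_network(net_config(in_channels = in_channels,
                           out_channels = out_channels,
                           final_activation = act, base_filters = bf,
                           input_shape = c(16, 16, 16), dropout = 0))
}

test_that("forward pass honours shape, range and normalization contracts", {
  set.seed(1)
  m6 <- tiny_net(6)
  x <- array(rnorm(16^3), c(16, 16, 16))
  p6 <- unet_forward(m6, x)
  expect_identical(dim(p6$scores), c(16L, 16L, 16L, 6L))
  expect_true(all(p6$scores >= 0 & p6$scores <= 1))

  m7 <- tiny_net(7)
  p7 <- unet_forward(m7, x)
  sums <- apply(p7$scores, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))

  # works across sizes divisible by 16
  x32 <- array(rnorm(32^3), c(32, 32, 32))
  expect_identical(dim(unet_forward(m6, x32)$scores)[1:3], c(32L, 32L, 32L))
  expect_error(unet_forward(m6, array(0, c(20, 20, 20))), "divisible")

  # deterministic inference
  expect_identical(unet_forward(m6, x)$scores, unet_forward(m6, x)$scores)

  # instance normalization cancels global affine intensity changes exactly
  # on constant inputs (the per-channel statistics absorb scale and shift)
  pc1 <- unet_forward(m6, array(1, c(16, 16, 16)))
  pc5 <- unet_forward(m6, array(5, c(16, 16, 16)))
  expect_equal(pc1$scores, pc5$scores, tolerance = 1e-3)
  expect_true(all(pc1$scores > 0 & pc1$scores < 1))
})

test_that("the decision rule implements the strict background threshold", {
  # sigmoid: all channels at 0.4 -> background
  p <- array(0.4, c(2, 2, 2, 6))
  lab <- predict_labels(p, mode = "sigmoid")
  expect_true(all(lab$data == 0L))
  # exactly 0.5 does not exceed the threshold
  p05 <- array(0.5, c(2, 2, 2, 6))
  expect_true(all(predict_labels(p05, mode = "sigmoid")$data == 0L))
  # a dominant WM channel wins
  p2 <- array(0.1, c(2, 2, 2, 6)); p2[, , , 3] <- 0.9
  expect_true(all(predict_labels(p2, mode = "sigmoid")$data == 3L))
  # softmax: uniform 1/7 ties resolve to the lowest channel = background
  p7 <- array(1 / 7, c(2, 2, 2, 7))
  expect_true(all(predict_labels(p7, mode = "softmax")$data == 0L))
  # softmax never invokes the threshold rule: argmax below 0.5 still labels
  p7b <- array(0.09, c(1, 1, 1, 7)); p7b[, , , 5] <- 0.46
  expect_identical(as.integer(predict_labels(p7b, mode = "softmax")$data), 4L)
})

test_that("predict_labels is idempotent through one-hot re-encoding", {
  set.seed(2)
  y <- random_labels(c(6, 6, 6), 0:6)
  oh <- one_hot(y, 1:6)
  lab <- predict_labels(oh, mode = "sigmoid")
  expect_identical(lab$data, array(as.integer(y), dim(y)))
})

test_that("network gradients track double-precision finite differences", {
  set.seed(3)
  cfg <- net_config(in_channels = 1, out_channels = 6, base_filters = 2,
                    input_shape = c(16, 16, 16), dropout = 0)
  m <- build_network(cfg)
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  y <- random_labels(c(16, 16, 16), 0:6)
  t_oh <- one_hot(y, 1:6)
  lg <- function(par) brainseg3d:::cpp_unet_loss_grad(
    unclass(cfg), par, x, c(16L, 16L, 16L), t_oh, "dice", numeric(0), 1L, TRUE)
  r <- lg(m$params)
  idx <- order(abs(r$grad), decreasing = TRUE)[seq(1, 2000, by = 97)]
  h <- 2e-2
  pair <- sapply(idx, function(i) {
    p1 <- m$params; p1[i] <- p1[i] + h
    p2 <- m$params; p2[i] <- p2[i] - h
    c(fd = (lg(p1)$loss - lg(p2)$loss) / (2 * h), an = r$grad[i])
  })
  rel <- abs(pair["fd", ] - pair["an", ]) /
    pmax(abs(pair["fd", ]), abs(pair["an", ]), 1e-6)
  # single-precision forward bounds the finite-difference resolution
  expect_lt(median(rel), 0.10)
  expect_gt(cor(pair["fd", ], pair["an", ]), 0.98)
})

test_that("skull stripping returns a binary mask on the input grid", {
  s <- small_subject()
  mski <- tiny_net(1)
  mask <- skull_strip(s$vol, mski)
  expect_identical(dim(mask$data), dim(s$vol$data))
  expect_true(all(mask$data %in% c(0L, 1L)))
  expect_error(skull_strip(s$vol, tiny_net(6)), "binary")
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_net(6)
  m$loss <- "dice"; m$use_prior <- TRUE
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  expect_identical(m2$loss, "dice")
  unlink(f)
})
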