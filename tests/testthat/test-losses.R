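test_that("soft Dice hits its extremes on perfect and anti-perfect predictions", {
  set.seed(2)
  y <- random_labels(c(4, 4, 4), 0:2)
  t <- one_hot(y, 1:2)
  expect_lt(soft_dice_loss(t, t), 1e-4)
  expect_gt(soft_dice_loss(1 - t, t), 0.999)
  expect_gte(soft_dice_loss(array(runif(4^3 * 2), c(4, 4, 4, 2)), t), 0)
})

test_that("soft Dice on uniform 0.5 matches a direct summation oracle", {
  set.seed(3)
  y <- random_labels(c(4, 4, 4), 0:3)
  t <- one_hot(y, 1:3)
  p <- array(0.5, dim(t))
  # independent oracle: direct per-class sums
  eps <- 1e-5
  per_class <- sapply(1:3, function(c) {
    tc <- t[, , , c]
    (2 * sum(0.5 * tc) + eps) / (sum(p[, , , c]) + sum(tc) + eps)
  })
  expect_equal(soft_dice_loss(p, t), 1 - mean(per_class), tolerance = 1e-12)
})

test_that("cross-entropy matches closed forms and a hand-computed example", {
  set.seed(4)
  y <- random_labels(c(4, 4, 4), 0:6)
  t <- one_hot(y, 0:6)
  expect_lt(cce_loss(t * 0.9999999 + 1e-9, t), 1e-4)
  u <- array(1 / 7, dim(t))
  expect_equal(cce_loss(u, t), log(7), tolerance = 1e-9)
  # 2-voxel hand example: p(correct) = 0.7 and 0.2
  p2 <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  t2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(cce_loss(p2, t2), -(log(0.7) + log(0.8)) / 2, tolerance = 1e-12)
})

test_that("median-frequency weights reproduce the worked examples", {
  sch <- c(background = 0L, c1 = 1L, c2 = 2L)
  m1 <- array(c(rep(0L, 100), rep(1L, 10), rep(2L, 50)), c(4, 5, 8))
  w <- median_frequency_weights(list(m1), scheme = sch)
  expect_equal(unname(w[c("background", "c1", "c2")]), c(1, 10, 2))

  # three maps: c1 counts (10, 20, 30), background (100, 100, 100)
  mk <- function(n1) array(c(rep(0L, 100), rep(1L, n1),
                             rep(2L, 60 - n1)), c(4, 5, 8))
  w3 <- median_frequency_weights(list(mk(10), mk(20), mk(30)), scheme = sch)
  expect_equal(unname(w3["c1"]), 100 / 20)

  # equal counts for all classes -> all weights 1
  me <- array(rep(0:3, each = 16), c(4, 4, 4))
  we <- median_frequency_weights(list(me),
                                 scheme = c(background = 0L, a = 1L,
                                            b = 2L, d = 3L))
  expect_true(all(we == 1))

  # a class absent everywhere errors with its name
  expect_error(median_frequency_weights(list(m1),
                                        scheme = c(sch, ghost = 9L)),
               "ghost")
})

test_that("weighted cross-entropy reduces to CCE and is linear in weights", {
  set.seed(5)
  y <- random_labels(c(4, 4, 4), 0:2)
  t <- one_hot(y, 0:2)
  p <- array(runif(prod(dim(t)), 0.05, 0.95), dim(t))
  expect_identical(wcce_loss(p, t, rep(1, 3)), cce_loss(p, t))
  expect_equal(wcce_loss(p, t, c(2, 4, 6)), 2 * wcce_loss(p, t, c(1, 2, 3)),
               tolerance = 1e-12)
  # 2-voxel manual oracle with weights (1, 3)
  p2 <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  t2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(wcce_loss(p2, t2, c(1, 3)),
               -(1 * log(0.7) + 3 * log(0.8)) / 2, tolerance = 1e-12)
  expect_error(wcce_loss(p2, t2, c(1, 2, 3)), "weight")
})

test_that("loss gradients agree with finite differences on 2^3 toys", {
  set.seed(6)
  dims <- c(2, 2, 2)
  y <- random_labels(dims, 0:2)
  fd_check <- function(lossfun, p, t, ...) {
    L <- lossfun(p, t, ..., with_grad = TRUE)
    g <- attr(L, "gradient")
    h <- 1e-6
    idx <- sample(length(p), 6)
    for (i in idx) {
      p1 <- p; p1[i] <- p1[i] + h
      p2 <- p; p2[i] <- p2[i] - h
      fd <- (as.numeric(lossfun(p1, t, ...)) -
               as.numeric(lossfun(p2, t, ...))) / (2 * h)
      denom <- max(abs(fd), abs(g[i]), 1e-8)
      expect_lt(abs(fd - g[i]) / denom, 1e-3)
    }
  }
  t6 <- one_hot(y, 1:2)
  p6 <- array(runif(prod(dim(t6)), 0.1, 0.9), dim(t6))
  fd_check(soft_dice_loss, p6, t6)
  t7 <- one_hot(y, 0:2)
  p7 <- array(runif(prod(dim(t7)), 0.1, 0.9), dim(t7))
  fd_check(cce_loss, p7, t7)
  fd_check(wcce_loss, p7, t7, weights = c(1, 3, 0.5))
})

test_that("soft Dice decreases monotonically toward the target", {
  set.seed(7)
  y <- random_labels(c(3, 3, 3), 0:2)
  t <- one_hot(y, 1:2)
  p0 <- array(runif(prod(dim(t)), 0.05, 0.95), dim(t))
  alphas <- seq(0, 1, by = 0.1)
  losses <- sapply(alphas, function(a)
    soft_dice_loss(p0 + a * (t - p0), t))
  expect_true(all(diff(losses) < 1e-10))
  expect_true(all(is.finite(losses)) && all(losses >= 0))
})
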