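test_that("plateau schedule halves after 10 and stops after 50 stalled epochs", {
  cfg <- train_config()
  flat <- rep(1.0, 60)
  tr <- schedule_trace(flat, cfg)
  # first decay event at epoch 11 (10 non-improving epochs after the first)
  expect_identical(which(tr$decayed)[1], 11L)
  expect_equal(tr$lr[11], 5e-4)          # decay takes effect from epoch 12
  expect_equal(tr$lr[12], 2.5e-4)
  # stop at exactly epoch 51
  expect_identical(attr(tr, "stop_epoch"), 51L)
  expect_identical(nrow(tr), 51L)
  # decays repeat every 10 stalled epochs until the stop
  expect_identical(which(tr$decayed), c(11L, 21L, 31L, 41L, 51L))
})

test_that("plateau schedule resets on improvement and lr never increases", {
  cfg <- train_config()
  vl <- c(1, 0.9, rep(0.95, 9), 0.8, rep(0.85, 12), 0.84)
  tr <- schedule_trace(vl, cfg)
  expect_true(all(diff(tr$lr) <= 0))
  expect_true(tr$improved[2])
  expect_true(tr$improved[12])
  # every decay is preceded by >= patience non-improving epochs
  for (e in which(tr$decayed)) {
    prev_improve <- max(c(0, which(tr$improved[seq_len(e)])))
    prev_decay <- max(c(0, setdiff(which(tr$decayed[seq_len(e - 1)]), e)))
    expect_gte(e - max(prev_improve, prev_decay, 1), cfg$lr_patience)
  }
  expect_identical(attr(tr, "best_epoch"), 12L)
})

# micro-cohort: 16^3 intensity-coded blobs, trivially learnable
micro_cohort <- function(n = 4, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    y <- array(0L, c(16, 16, 16))
    cx <- sample(6:10, 1)
    y[(cx - 3):(cx + 3), 5:12, 5:12] <- 1L
    y[(cx - 1):(cx + 1), 7:10, 7:10] <- 2L
    x <- array(rnorm(16^3, 0, 0.1), c(16, 16, 16))
    x <- x + (y == 1) * 1 + (y == 2) * 2
    list(x = array(x, c(16, 16, 16, 1)), y = y)
  }))
}

test_that("training reduces validation loss and logs schedule events", {
  cohort <- micro_cohort(4)
  cfg <- train_config(max_epochs = 8, base_filters = 2, loss = "dice",
                      initial_lr = 5e-3, dropout = 0, seed = 1)
  ck <- train(cohort, cfg)
  expect_s3_class(ck, "bs_checkpoint")
  expect_lt(tail(ck$log$val_loss, 1), ck$log$val_loss[1])
  expect_true(all(diff(ck$log$lr) <= 0))
  expect_true(ck$model$trained)
  # retained checkpoint achieves the best observed validation loss
  vbest <- mean(vapply(ck$val_idx, function(i)
    brainseg3d:::eval_loss(ck$model, cohort[[i]], "dice", 1:6, NULL),
    numeric(1)))
  expect_lte(vbest, min(ck$log$val_loss) + 10 * cfg$improvement_tol)
  # reproducibility: identical seed and config give identical logs
  ck2 <- train(cohort, cfg)
  expect_identical(ck$log$train_loss, ck2$log$train_loss)
  expect_identical(ck$log$val_loss, ck2$log$val_loss)
  expect_identical(ck$model$params, ck2$model$params)
  expect_error(train(cohort[1], cfg), "at least 2")
})

test_that("wcce training derives median-frequency weights from the cohort", {
  cohort <- micro_cohort(3)
  cfg <- train_config(max_epochs = 2, base_filters = 2, loss = "wcce",
                      dropout = 0, seed = 2)
  # micro cohort uses codes 0..2 of the 7-class scheme; classes 3..6 are
  # absent everywhere, so weight derivation must fail loudly
  expect_error(train(cohort, cfg), "median voxel count is zero")
})

test_that("zero-epoch transfer returns the base weights unchanged", {
  cohort <- micro_cohort(4)
  base <- train(cohort, train_config(max_epochs = 2, base_filters = 2,
                                     dropout = 0, loss = "dice", seed = 3))
  ck0 <- transfer_finetune(base, cohort,
                           train_config(max_epochs = 0, base_filters = 2))
  expect_identical(ck0$model$params, base$model$params)
  # loss / prior settings inherited from the base model
  expect_identical(ck0$cfg$loss, "dice")
  expect_identical(ck0$cfg$use_prior, base$cfg$use_prior)
  # channel mismatch is rejected
  bad <- lapply(cohort, function(s) {
    s$x <- array(rep(s$x, 2), c(16, 16, 16, 2)); s
  })
  expect_error(transfer_finetune(base, bad, train_config(max_epochs = 1)),
               "in_channels")
})

test_that("fine-tuning from a base model improves on new-style subjects", {
  base <- train(micro_cohort(4, seed = 1),
                train_config(max_epochs = 6, base_filters = 2, dropout = 0,
                             initial_lr = 5e-3, loss = "dice", seed = 4))
  new_cohort <- micro_cohort(4, seed = 99)
  ck <- transfer_finetune(base, new_cohort,
                          train_config(max_epochs = 4, base_filters = 2,
                                       dropout = 0, initial_lr = 5e-3,
                                       seed = 5))
  expect_lte(min(ck$log$val_loss), ck$log$val_loss[1] + 1e-9)
})

test_that("leave-one-out transfer bookkeeping is disjoint and exhaustive", {
  cohort <- micro_cohort(7, seed = 2)
  base <- train(cohort[1:4], train_config(max_epochs = 1, base_filters = 2,
                                          dropout = 0, loss = "dice", seed = 6))
  res <- loocv_transfer(base, cohort,
                        train_config(max_epochs = 0, base_filters = 2))
  expect_equal(nrow(res$folds), 7)
  expect_identical(sort(res$folds$test), 1:7)
  for (i in 1:7) {
    tr <- as.integer(strsplit(res$folds$train[i], ",")[[1]])
    expect_length(tr, 5)                       # 5 train / 1 val / 1 test
    expect_false(res$folds$test[i] %in% tr)
    expect_false(res$folds$val[i] %in% tr)
    expect_false(res$folds$val[i] == res$folds$test[i])
  }
  expect_length(res$predictions, 7)
  expect_true(all(!vapply(res$predictions, is.null, logical(1))))

  # n = 3 degenerate: 1 train / 1 val / 1 test
  res3 <- loocv_transfer(base, cohort[1:3],
                         train_config(max_epochs = 0, base_filters = 2))
  expect_length(as.integer(strsplit(res3$folds$train[1], ",")[[1]]), 1)
  expect_error(loocv_transfer(base, cohort[1:2],
                              train_config(max_epochs = 0)), "at least 3")
})
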