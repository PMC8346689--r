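#' Training configuration
#'
#' Optimization schedule: Adam from a seeded random initialization, initial
#' learning rate 5e-4, halved after 10 epochs without improvement of the
#' validation loss, stopped after 50 epochs without improvement, batch size
#' 1, and an inner 90/10 subject-level train/validation split for plateau
#' detection. "Improvement" means a validation loss strictly below the best
#' so far minus `improvement_tol`.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay factor (in (0, 1)).
#' @param lr_patience Non-improving epochs before a decay.
#' @param early_stop Non-improving epochs before stopping.
#' @param inner_split Train/validation fractions of the inner split.
#' @param max_epochs Hard cap on epochs (the schedule may stop earlier).
#' @param loss One of "dice", "cce", "wcce".
#' @param use_prior Spatial prior as a second input channel?
#' @param base_filters,dropout,negative_slope Network settings.
#' @param augment `NULL`, or [augment_params()] ranges applied per step.
#' @param weight_decay L2 regularization of convolution weights (not biases
#'   or norm parameters), added to the gradient before the Adam update;
#'   keeps logits bounded so the decision rule stays informative. The
#'   default follows the network's source architecture.
#' @param improvement_tol Tolerance defining an improvement.
#' @param seed Seed controlling initialization, splits, shuffling, dropout
#'   and augmentation.
#' @return A `bs_train_config`.
#' @export
train_config <- function(initial_lr = 5e-4, lr_decay_factor = 0.5,
                         lr_patience = 10L, early_stop = 50L,
                         inner_split = c(0.9, 0.1), max_epochs = 100L,
                         loss = c("dice", "cce", "wcce"), use_prior = TRUE,
                         base_filters = 8L, dropout = 0.3,
                         negative_slope = 0.01, augment = NULL,
                         weight_decay = 1e-5,
                         improvement_tol = 1e-5, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(lr_decay_factor > 0, lr_decay_factor < 1,
            lr_patience < early_stop)
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop = as.integer(early_stop),
                 batch_size = 1L, inner_split = inner_split,
                 max_epochs = as.integer(max_epochs), loss = loss,
                 use_prior = use_prior,
                 base_filters = as.integer(base_filters), dropout = dropout,
                 negative_slope = negative_slope, augment = augment,
                 weight_decay = weight_decay,
                 improvement_tol = improvement_tol, seed = as.integer(seed)),
            class = "bs_train_config")
}

#' Plateau schedule semantics on a validation-loss trace
#'
#' Pure function implementing the learning-rate decay and early-stopping
#' rules: after each epoch's validation, a non-improving epoch increments
#' both counters; when the decay counter reaches `lr_patience` the learning
#' rate is multiplied by `lr_decay_factor` (event recorded at that epoch,
#' effective from the next) and the decay counter resets; when the stop
#' counter reaches `early_stop` training stops at that epoch.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param cfg A [train_config()].
#' @return data.frame with per-epoch `lr` (in effect during the epoch),
#'   `improved`, `decayed` flags, and attributes `stop_epoch` (NA if never
#'   triggered) and `best_epoch`.
#' @export
schedule_trace <- function(val_losses, cfg = train_config()) {
  n <- length(val_losses)
  lr <- cfg$initial_lr
  best <- Inf
  best_epoch <- NA_integer_
  since_improve_decay <- 0L
  since_improve_stop <- 0L
  out <- data.frame(epoch = seq_len(n), lr = NA_real_, val_loss = val_losses,
                    improved = FALSE, decayed = FALSE)
  stop_epoch <- NA_integer_
  for (e in seq_len(n)) {
    out$lr[e] <- lr
    if (is.finite(best) && val_losses[e] < best - cfg$improvement_tol ||
        !is.finite(best)) {
      # first epoch sets the reference without counting as an improvement
      if (is.finite(best)) {
        out$improved[e] <- TRUE
        since_improve_decay <- 0L
        since_improve_stop <- 0L
      }
      best <- val_losses[e]
      best_epoch <- e
    } else {
      since_improve_decay <- since_improve_decay + 1L
      since_improve_stop <- since_improve_stop + 1L
      if (since_improve_decay >= cfg$lr_patience) {
        lr <- lr * cfg$lr_decay_factor
        out$decayed[e] <- TRUE
        since_improve_decay <- 0L
      }
      if (since_improve_stop >= cfg$early_stop) {
        stop_epoch <- e
        break
      }
    }
  }
  out <- out[!is.na(out$lr), , drop = FALSE]
  attr(out, "stop_epoch") <- stop_epoch
  attr(out, "best_epoch") <- best_epoch
  out
}

# incremental scheduler used inside train(); mirrors schedule_trace()
make_scheduler <- function(cfg) {
  env <- new.env(parent = emptyenv())
  env$lr <- cfg$initial_lr
  env$best <- Inf
  env$best_epoch <- NA_integer_
  env$decay_ctr <- 0L
  env$stop_ctr <- 0L
  env$first_seen <- FALSE
  list(
    lr = function() env$lr,
    observe = function(epoch, val) {
      improved <- FALSE
      if (!env$first_seen) {
        env$first_seen <- TRUE
        env$best <- val
        env$best_epoch <- epoch
        is_best <- TRUE
      } else if (val < env$best - cfg$improvement_tol) {
        improved <- TRUE
        is_best <- TRUE
        env$best <- val
        env$best_epoch <- epoch
        env$decay_ctr <- 0L
        env$stop_ctr <- 0L
      } else {
        is_best <- FALSE
        env$decay_ctr <- env$decay_ctr + 1L
        env$stop_ctr <- env$stop_ctr + 1L
      }
      decayed <- FALSE
      if (!is_best && env$decay_ctr >= cfg$lr_patience) {
        env$lr <- env$lr * cfg$lr_decay_factor
        env$decay_ctr <- 0L
        decayed <- TRUE
      }
      stop_now <- !is_best && env$stop_ctr >= cfg$early_stop
      list(improved = improved, is_best = is_best, decayed = decayed,
           stop = stop_now, best_epoch = env$best_epoch)
    })
}

# one-hot target channels for a loss mode
target_codes <- function(loss, out_channels) {
  if (out_channels == 1) return(1L)
  if (loss == "dice") 1:6 else 0:6
}

# network configuration implied by a training configuration
net_config_for <- function(cfg, in_channels, input_shape, out_channels = NULL) {
  if (is.null(out_channels))
    out_channels <- if (cfg$loss == "dice") 6L else 7L
  net_config(in_channels = in_channels, out_channels = out_channels,
             final_activation = if (cfg$loss == "dice" || out_channels == 1)
               "sigmoid" else "softmax",
             base_filters = cfg$base_filters, input_shape = input_shape,
             negative_slope = cfg$negative_slope, dropout = cfg$dropout,
             seed = cfg$seed)
}

# evaluation-mode loss of one subject (no dropout, no augmentation)
eval_loss <- function(model, subj, loss, codes, weights) {
  t_oh <- one_hot(subj$y, codes)
  r <- cpp_unet_loss_grad(unclass(model$config), model$params,
                          as_net_input(subj$x, model$config$in_channels),
                          dim(subj$y), t_oh, loss,
                          if (is.null(weights)) numeric(0)
                          else as.numeric(weights),
                          0L, FALSE)
  r$loss
}

#' Train the segmentation network
#'
#' Adam optimization with the plateau schedule of [train_config()]. The
#' cohort is split at subject level into inner training and validation
#' subsets (seeded, once per run) unless `val_idx` is given; the checkpoint
#' with the best validation loss is retained.
#'
#' @param cohort List of subjects; each a list with `x` (input array
#'   (X,Y,Z,C) or (X,Y,Z)) and `y` (integer ground-truth label array).
#' @param cfg A [train_config()].
#' @param model Optional pre-built/pre-trained `bs_unet` to continue from.
#' @param val_idx Optional explicit validation subject indices.
#' @param out_channels Override output channels (1 for skull-strip mode).
#' @param verbose Print per-epoch progress?
#' @return A `bs_checkpoint`: `model` (best weights), `log` (per-epoch
#'   data.frame), `cfg`, `weights` (class weights if WCCE), `val_idx`.
#' @export
train <- function(cohort, cfg = train_config(), model = NULL, val_idx = NULL,
                  out_channels = NULL, verbose = FALSE) {
  if (length(cohort) < 2) stop("need at least 2 training subjects")
  x1 <- cohort[[1]]$x
  in_channels <- if (length(dim(x1)) == 4) dim(x1)[4] else 1L
  input_shape <- dim(x1)[1:3]
  if (is.null(model)) {
    model <- build_network(net_config_for(cfg, in_channels, input_shape,
                                          out_channels))
  }
  codes <- target_codes(cfg$loss, model$config$out_channels)
  weights <- NULL
  if (cfg$loss == "wcce") {
    weights <- median_frequency_weights(
      lapply(cohort, function(s) s$y),
      scheme = tissue_scheme())
  }
  n <- length(cohort)
  with_seed(cfg$seed, {
    if (is.null(val_idx)) {
      n_val <- max(1L, round(n * cfg$inner_split[2]))
      val_idx <- sort(sample.int(n, n_val))
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) == 0) stop("inner split left no training subjects")
    sched <- make_scheduler(cfg)
    theta <- model$params
    wd_mask <- if (is.null(cfg$weight_decay) || cfg$weight_decay <= 0) NULL
      else rep(model$param_info$type == "conv", model$param_info$length)
    mvec <- numeric(length(theta))
    vvec <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    step <- 0L
    best_params <- theta
    log_rows <- vector("list", cfg$max_epochs)
    n_epochs <- 0L
    wnum <- if (is.null(weights)) numeric(0) else as.numeric(weights)
    for (epoch in seq_len(cfg$max_epochs)) {
      t0 <- proc.time()[3]
      lr_now <- sched$lr()
      ord <- train_idx[sample.int(length(train_idx))]
      tr_losses <- numeric(length(ord))
      for (k in seq_along(ord)) {
        subj <- cohort[[ord[k]]]
        x <- as_net_input(subj$x, in_channels)
        y <- subj$y
        if (!is.null(cfg$augment)) {
          aug <- augment_subject(x, y, cfg$augment, seed = sample.int(2^30, 1))
          x <- aug$x; y <- aug$y
        }
        t_oh <- one_hot(y, codes)
        r <- cpp_unet_loss_grad(unclass(model$config), theta, x,
                                dim(y), t_oh, cfg$loss, wnum,
                                sample.int(2^30, 1), TRUE)
        if (!is.finite(r$loss))
          stop("non-finite training loss at epoch ", epoch,
               ", subject ", ord[k], "; aborting")
        tr_losses[k] <- r$loss
        step <- step + 1L
        g <- r$grad
        if (!is.null(wd_mask))   # L2 regularization of convolution weights
          g[wd_mask] <- g[wd_mask] + cfg$weight_decay * theta[wd_mask]
        mvec <- b1 * mvec + (1 - b1) * g
        vvec <- b2 * vvec + (1 - b2) * g^2
        mhat <- mvec / (1 - b1^step)
        vhat <- vvec / (1 - b2^step)
        theta <- theta - lr_now * mhat / (sqrt(vhat) + adam_eps)
      }
      model$params <- theta
      val_losses <- vapply(val_idx, function(i)
        eval_loss(model, cohort[[i]], cfg$loss, codes, weights), numeric(1))
      vloss <- mean(val_losses)
      ev <- sched$observe(epoch, vloss)
      if (ev$is_best) best_params <- theta
      n_epochs <- epoch
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(tr_losses), val_loss = vloss,
        lr = lr_now, improved = ev$improved, decayed = ev$decayed,
        wall_s = proc.time()[3] - t0)
      if (verbose)
        message(sprintf("epoch %d train %.4f val %.4f lr %.2e", epoch,
                        mean(tr_losses), vloss, lr_now))
      if (ev$stop) break
    }
    model$params <- best_params
    model$trained <- TRUE
    model$loss <- cfg$loss
    model$use_prior <- cfg$use_prior
    structure(list(model = model,
                   log = do.call(rbind, log_rows[seq_len(n_epochs)]),
                   cfg = cfg, weights = weights, val_idx = val_idx),
              class = "bs_checkpoint")
  })
}

# apply one random affine to the stacked input channels + labels; the prior
# channel (any channel beyond the first) is label-like, so it is transformed
# with nearest-neighbour sampling
augment_subject <- function(x, y, params, seed) {
  dims <- dim(y)
  M <- with_seed(seed, random_affine_matrix(dims, params))
  coords <- apply_affine_coords(solve(M), voxel_grid(dims))
  C <- dim(x)[4]
  out <- x
  out[, , , 1] <- array(cpp_resample(x[, , , 1], dims, coords, 1L, 0), dims)
  if (C > 1) for (ch in 2:C)
    out[, , , ch] <- array(cpp_resample(x[, , , ch], dims, coords, 0L, 0), dims)
  yout <- array(cpp_warp_labels(y, dims, coords, 0.2), dims)
  list(x = out, y = yout)
}

#' Transfer learning: fine-tune from a checkpoint
#'
#' Initializes from the base model's weights and trains on a new cohort with
#' the same loss and prior configuration as the base model (inherited; the
#' supplied `cfg` controls schedule/epochs). With `max_epochs = 0` the
#' weights are returned unchanged.
#'
#' @param base A `bs_checkpoint` or `bs_unet`.
#' @param cohort New cohort (same structure as for [train()]).
#' @param cfg A [train_config()]; its `loss`/`use_prior` are overridden by
#'   the base model's settings.
#' @param val_idx Optional explicit validation indices.
#' @return A `bs_checkpoint`.
#' @export
transfer_finetune <- function(base, cohort, cfg = train_config(),
                              val_idx = NULL) {
  model <- if (inherits(base, "bs_checkpoint")) base$model else base
  stopifnot(inherits(model, "bs_unet"))
  x1 <- cohort[[1]]$x
  in_channels <- if (length(dim(x1)) == 4) dim(x1)[4] else 1L
  if (in_channels != model$config$in_channels)
    stop("config mismatch between base model and cohort: in_channels (",
         model$config$in_channels, " vs ", in_channels, ")")
  # inherit the base model's loss / prior configuration
  if (!is.null(model$loss)) cfg$loss <- model$loss
  if (!is.null(model$use_prior)) cfg$use_prior <- model$use_prior
  if (cfg$max_epochs == 0) {
    return(structure(list(model = model, log = NULL, cfg = cfg,
                          weights = NULL, val_idx = val_idx),
                     class = "bs_checkpoint"))
  }
  train(cohort, cfg, model = model, val_idx = val_idx)
}

#' Leave-one-out cross-validated transfer learning
#'
#' For each of the `n` subjects: fine-tune the base model on `n - 2`
#' subjects, monitor validation on 1 (round-robin: the subject following the
#' held-out one), and predict the held-out subject with the model for which
#' it was left out.
#'
#' @param base A `bs_checkpoint` or `bs_unet` (the pretrained model).
#' @param cohort List of subjects (n >= 3), as for [train()].
#' @param cfg A [train_config()] for each fold.
#' @return List with `folds` (data.frame of fold assignments),
#'   `predictions` (one `bs_labelmap`-style array per subject) and
#'   `val_losses`.
#' @export
loocv_transfer <- function(base, cohort, cfg = train_config()) {
  n <- length(cohort)
  if (n < 3) stop("leave-one-out transfer needs at least 3 subjects")
  folds <- data.frame(fold = seq_len(n), test = seq_len(n),
                      val = (seq_len(n) %% n) + 1L)
  preds <- vector("list", n)
  vls <- numeric(n)
  for (i in seq_len(n)) {
    test_i <- folds$test[i]
    val_i <- folds$val[i]
    keep <- setdiff(seq_len(n), test_i)
    sub_cohort <- cohort[keep]
    val_pos <- match(val_i, keep)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    ck <- transfer_finetune(base, sub_cohort, cfg_i, val_idx = val_pos)
    model <- ck$model
    pr <- unet_forward(model, cohort[[test_i]]$x)
    preds[[test_i]] <- predict_labels(pr)
    vls[i] <- if (is.null(ck$log)) NA_real_ else min(ck$log$val_loss)
  }
  folds$train <- vapply(seq_len(n), function(i)
    paste(setdiff(seq_len(n), c(folds$test[i], folds$val[i])),
          collapse = ","), character(1))
  list(folds = folds, predictions = preds, val_losses = vls)
}
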