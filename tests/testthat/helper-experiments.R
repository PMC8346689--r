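# Desk-scale study conditions shared by the heavier acceptance tests.
# Phantom cohorts of 36^3 voxels at 4 mm, a 32^3 network grid, 8 (or 4)
# base filters, soft Dice loss, and the small-cohort optimizer settings
# (initial_lr 1e-2, L2 3e-3); see the methods vignette.

experiment_reg_config <- function() {
  reg_config(levels = c(4, 2), rigid_iters = c(60, 30),
             affine_iters = c(40, 20), demons_iters = c(30, 15))
}

prior_reg_config <- function() {
  reg_config(levels = c(4, 2, 1), rigid_iters = c(60, 30, 0),
             affine_iters = c(40, 20, 10), demons_iters = c(25, 15, 8))
}

# 8-subject cohort, 6 train / 2 held out, soft Dice + prior at 32^3,
# 8 base filters; returns held-out native-space quality vs the
# registration-only baseline
run_tiny_training <- function() {
  spec <- phantom_spec(grid_shape = c(36, 36, 36), spacing_mm = c(4, 4, 4))
  tpl <- make_template(spec)
  subjects <- lapply(1:8, function(i) sample_subject(tpl, spec, seed = 100 + i))
  pcfg <- pipeline_config(tissue_model = structure(list(), class = "bs_unet"),
                          template = tpl$vol, template_labels = tpl$labels,
                          use_prior = TRUE, cube = 32L, margin = 2L,
                          reg_config = experiment_reg_config())
  prep <- prepare_cohort(subjects, pcfg)
  baseline <- rowMeans(sapply(7:8, function(j) sapply(1:6, function(k)
    dice(prep[[j]]$prior_native, prep[[j]]$native_labels, k))))
  cfg <- train_config(max_epochs = 100, base_filters = 8, loss = "dice",
                      initial_lr = 1e-2, weight_decay = 3e-3, seed = 42)
  ck <- train(prep[1:6], cfg, val_idx = c(5L, 6L))
  dn <- sapply(7:8, function(j) {
    pl <- predict_labels(unet_forward(ck$model, prep[[j]]$x))
    pn <- to_native(pl, prep[[j]]$record)
    sapply(1:6, function(k) dice(pn, prep[[j]]$native_labels, k))
  })
  list(overall = mean(colMeans(dn)), class_means = rowMeans(dn),
       baseline = baseline, checkpoint = ck, prepared = prep)
}

# Low-contrast prior-effect experiment: isointense deep gray
# (contrast_scale = 0), one with-prior and one without-prior model per
# seed, deep-gray Dice on a held-out subject
run_prior_effect <- function(seeds = 1:5, max_epochs = 60L) {
  res <- sapply(seeds, function(sd) {
    spec <- phantom_spec(grid_shape = c(36, 36, 36), spacing_mm = c(4, 4, 4),
                         contrast_scale = 0)
    tpl <- make_template(spec)
    subjects <- lapply(1:5, function(i)
      sample_subject(tpl, spec, seed = sd * 1000 + i))
    pcfg <- pipeline_config(
      tissue_model = structure(list(), class = "bs_unet"),
      template = tpl$vol, template_labels = tpl$labels,
      use_prior = TRUE, cube = 32L, margin = 2L,
      reg_config = prior_reg_config())
    prep_w <- prepare_cohort(subjects, pcfg)
    prep_wo <- lapply(prep_w, function(s) {
      s$x <- s$x[, , , 1, drop = FALSE]
      s
    })
    cfg <- train_config(max_epochs = max_epochs, base_filters = 4,
                        loss = "dice", initial_lr = 1e-2,
                        weight_decay = 3e-3, dropout = 0, seed = 7)
    ck_w <- train(prep_w[1:4], cfg, val_idx = 4L)
    ck_wo <- train(prep_wo[1:4], cfg, val_idx = 4L)
    d4 <- function(ck, prep) {
      pl <- predict_labels(unet_forward(ck$model, prep[[5]]$x))
      pn <- to_native(pl, prep[[5]]$record)
      dice(pn, prep[[5]]$native_labels, 4)
    }
    c(with = d4(ck_w, prep_w), without = d4(ck_wo, prep_wo))
  })
  colnames(res) <- paste0("seed", seeds)
  res
}
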