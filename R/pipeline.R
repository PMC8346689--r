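#' Pipeline configuration
#'
#' Wiring of the fully automated segmentation pipeline: skull-strip -> crop
#' -> cubic resampling -> z-score -> (spatial prior on the network grid) ->
#' inference -> decision rule -> native-space resampling.
#'
#' @param tissue_model `bs_unet` or `bs_checkpoint` for tissue segmentation.
#' @param skullstrip_model Optional binary-mode `bs_unet`; when `NULL` the
#'   foreground (intensity > 0) is used as the brain mask.
#' @param template,template_labels Template `bs_volume` / `bs_labelmap`
#'   (required when `use_prior`).
#' @param use_prior Build and feed the spatial prior channel?
#' @param cube Network grid edge length.
#' @param margin Crop margin in voxels.
#' @param reg_config Registration settings for the prior.
#' @param prior_sigma Label-interpolation sigma (voxels) for the prior.
#' @return A `bs_pipeline_config`.
#' @export
pipeline_config <- function(tissue_model, skullstrip_model = NULL,
                            template = NULL, template_labels = NULL,
                            use_prior = TRUE, cube = 128L, margin = 2L,
                            reg_config = brainseg3d::reg_config(),
                            prior_sigma = 0.2) {
  if (inherits(tissue_model, "bs_checkpoint")) tissue_model <- tissue_model$model
  if (use_prior && (is.null(template) || is.null(template_labels)))
    stop("use_prior requires template and template_labels")
  structure(list(tissue_model = tissue_model,
                 skullstrip_model = skullstrip_model,
                 template = template, template_labels = template_labels,
                 use_prior = use_prior, cube = as.integer(cube),
                 margin = as.integer(margin), reg_config = reg_config,
                 prior_sigma = prior_sigma),
            class = "bs_pipeline_config")
}

# Preprocess one subject onto the network grid. Returns the network input
# tensor (with prior channel if requested), the crop record, and the prior
# in native space (which doubles as the registration baseline).
prepare_subject <- function(vol, cfg, labels = NULL) {
  mask <- NULL
  if (!is.null(cfg$skullstrip_model)) {
    ss <- skull_strip(vol, cfg$skullstrip_model)
    mask <- ss$data > 0
    vol <- bs_volume(vol$data * mask, affine = vol$affine)
  }
  cr <- crop_foreground(vol, labels = labels, mask = mask, margin = cfg$margin)
  cube_vol <- resample_to_cube(cr$vol, cfg$cube, record = cr$record)
  record <- attr(cube_vol, "record")
  zs <- zscore(cube_vol)
  x <- array(zs$data, dim = c(rep(cfg$cube, 3L), 1L))
  prior_native <- NULL
  if (cfg$use_prior) {
    chain <- register(vol, cfg$template, config = cfg$reg_config)
    prior_native <- warp_labels(cfg$template_labels, chain,
                                sigma_vox = cfg$prior_sigma)
    attr(prior_native, "chain") <- chain
    # compose network-grid coords -> native voxel -> template, sampling the
    # smoothed template labels once (no double interpolation)
    g <- voxel_grid(rep(cfg$cube, 3L))
    crop_dims <- record$hi - record$lo + 1L
    nat <- sweep(sweep(g, 2, 0.5, "+"), 2, crop_dims / cfg$cube, "*") - 0.5
    nat <- sweep(nat, 2, record$lo - 1L, "+")
    prior_cube <- warp_labels(cfg$template_labels, chain,
                              sigma_vox = cfg$prior_sigma, coords = nat,
                              out_dims = rep(cfg$cube, 3L))
    n_classes <- sum(cfg$template_labels$scheme != 0)
    x <- array(c(x, prior_cube$data / n_classes),
               dim = c(rep(cfg$cube, 3L), 2L))
  }
  y <- NULL
  if (!is.null(cr$labels))
    y <- resample_to_cube(cr$labels, cfg$cube)$data
  list(x = x, y = y, record = record, prior_native = prior_native,
       native_labels = labels)
}

#' Segment a T1 volume end to end
#'
#' Runs the full automated pipeline on one subject and returns the
#' native-space prediction together with a QC sidecar (crop bounds, stage
#' timings, configuration summary). Deterministic given inputs.
#'
#' @param t1 `bs_volume` or path to a NIfTI file.
#' @param cfg A [pipeline_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_seg.nii.gz` and `<prefix>_qc.json`.
#' @return `bs_labelmap` in native space, with attributes `qc` and
#'   `prior_native`.
#' @export
segment <- function(t1, cfg, out_prefix = NULL) {
  if (is.character(t1)) t1 <- read_volume(t1)
  if (!inherits(cfg$tissue_model, "bs_unet"))
    stop("cfg$tissue_model must be a bs_unet")
  timings <- c()
  tic <- function() proc.time()[3]
  t0 <- tic()
  prep <- prepare_subject(t1, cfg)
  timings["preprocess_s"] <- tic() - t0
  t0 <- tic()
  probs <- unet_forward(cfg$tissue_model, prep$x)
  pred_cube <- predict_labels(probs)
  timings["inference_s"] <- tic() - t0
  t0 <- tic()
  pred_native <- to_native(pred_cube, prep$record)
  timings["postprocess_s"] <- tic() - t0
  qc <- list(crop_start = prep$record$lo - 1L, crop_stop = prep$record$hi,
             original_shape = prep$record$original_shape,
             cube = cfg$cube, use_prior = cfg$use_prior,
             loss = cfg$tissue_model$loss,
             timings_s = as.list(timings))
  attr(pred_native, "qc") <- qc
  attr(pred_native, "prior_native") <- prep$prior_native
  if (!is.null(out_prefix)) {
    write_labelmap(pred_native, paste0(out_prefix, "_seg.nii.gz"))
    jsonlite::write_json(qc, paste0(out_prefix, "_qc.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  pred_native
}

#' Prepare a phantom cohort for training
#'
#' Loads (or takes in-memory) subjects, preprocesses each onto the network
#' grid and attaches the ground truth; priors are built per subject when
#' requested.
#'
#' @param subjects List of lists with `vol` and `labels` (and optionally
#'   `lesions`).
#' @param cfg A [pipeline_config()] (its `tissue_model` may be `NULL` at
#'   this stage; only geometry/prior settings are used).
#' @return List of prepared subjects (fields `x`, `y`, `record`,
#'   `prior_native`, `native_labels`).
#' @export
prepare_cohort <- function(subjects, cfg) {
  lapply(subjects, function(s)
    c(prepare_subject(s$vol, cfg, labels = s$labels),
      list(lesions = s$lesions)))
}

#' Train and evaluate the loss-function / prior design matrix
#'
#' Trains one model per requested (loss, prior) combination on the prepared
#' cohort and evaluates each on the held-out subjects, producing a
#' tissue-wise mean +/- SD table and pairwise Z comparisons of the
#' per-subject overall Dice.
#'
#' @param prepared_with,prepared_without Prepared cohorts (from
#'   [prepare_cohort()]) with and without the prior channel; either may be
#'   `NULL` if that arm is not requested.
#' @param test_idx Indices of held-out subjects (evaluated, never trained).
#' @param losses Subset of `c("dice", "cce", "wcce")`.
#' @param prior Subset of `c(TRUE, FALSE)`.
#' @param cfg Base [train_config()].
#' @return List with `table` (one row per configuration x tissue),
#'   `overall` (per-config overall Dice mean/SD), `z` (pairwise
#'   comparisons), `checkpoints`.
#' @export
run_design_matrix <- function(prepared_with, prepared_without, test_idx,
                              losses = c("dice", "cce", "wcce"),
                              prior = c(TRUE, FALSE),
                              cfg = train_config()) {
  combos <- expand.grid(loss = losses, prior = prior,
                        stringsAsFactors = FALSE)
  rows <- list(); overall <- list(); cks <- list()
  dice_by_subj <- list()
  for (i in seq_len(nrow(combos))) {
    lo <- combos$loss[i]; pr <- combos$prior[i]
    prepared <- if (pr) prepared_with else prepared_without
    if (is.null(prepared)) stop("prepared cohort missing for prior=", pr)
    train_set <- prepared[setdiff(seq_along(prepared), test_idx)]
    cfg_i <- cfg
    cfg_i$loss <- lo
    cfg_i$use_prior <- pr
    ck <- train(train_set, cfg_i)
    preds <- lapply(test_idx, function(j) {
      pl <- predict_labels(unet_forward(ck$model, prepared[[j]]$x))
      to_native(pl, prepared[[j]]$record)
    })
    truths <- lapply(test_idx, function(j) prepared[[j]]$native_labels)
    rep_i <- evaluate_cohort(preds, truths)
    key <- paste0(lo, if (pr) "+prior" else "-prior")
    rows[[key]] <- cbind(config = key, loss = lo, prior = pr, rep_i$summary)
    overall[[key]] <- data.frame(config = key,
                                 dice_mean = rep_i$overall$dice_mean,
                                 dice_sd = rep_i$overall$dice_sd)
    dice_by_subj[[key]] <- rep_i$overall$per_subject
    cks[[key]] <- ck
  }
  zs <- list()
  keys <- names(dice_by_subj)
  if (length(keys) > 1 && length(dice_by_subj[[1]]) >= 2) {
    for (a in seq_along(keys)) for (b in seq_along(keys)) {
      if (a >= b) next
      zs[[paste(keys[a], "vs", keys[b])]] <-
        z_compare(dice_by_subj[[keys[a]]], dice_by_subj[[keys[b]]])
    }
  }
  list(table = do.call(rbind, rows), overall = do.call(rbind, overall),
       z = zs, checkpoints = cks)
}
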