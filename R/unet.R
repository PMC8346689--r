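#' Network configuration
#'
#' Settings of the 3D encoder-decoder segmentation network: 4 downsampling
#' blocks (each a strided convolution followed by a residual context module)
#' and 4 upsampling blocks (nearest-neighbour upscale + convolution, skip
#' concatenation, localization module), 3x3x3 kernels everywhere, instance
#' normalization and leaky ReLU after every convolution, and deep
#' supervision: 1x1x1 side outputs of the final three upsampling blocks are
#' upsampled to the input shape, summed, and passed through the final
#' activation.
#'
#' Mode invariants: 6 output channels pair with sigmoid activation (tissue
#' channels only; background is implicit via the decision rule), 7 with
#' softmax (explicit background channel), and 1 with sigmoid (binary
#' skull-stripping mode).
#'
#' @param in_channels 1 (T1 only) or 2 (T1 + spatial prior).
#' @param out_channels 6, 7 or 1.
#' @param final_activation "sigmoid" or "softmax".
#' @param base_filters Filters at the highest resolution (doubled per level).
#' @param input_shape Spatial input shape; each axis divisible by 16.
#' @param negative_slope Leaky ReLU slope.
#' @param dropout Dropout rate inside context modules (training only).
#' @param seed Seed for weight initialization.
#' @return A `bs_net_config`.
#' @export
net_config <- function(in_channels = 2, out_channels = 6,
                       final_activation = c("sigmoid", "softmax"),
                       base_filters = 16, input_shape = c(128, 128, 128),
                       negative_slope = 0.01, dropout = 0.3, seed = 42L) {
  final_activation <- match.arg(final_activation)
  if (out_channels == 6 && final_activation != "sigmoid")
    stop("6 output channels require sigmoid activation")
  if (out_channels == 7 && final_activation != "softmax")
    stop("7 output channels require softmax activation")
  if (out_channels == 1 && final_activation != "sigmoid")
    stop("binary (skull-strip) mode requires sigmoid activation")
  if (!out_channels %in% c(1, 6, 7))
    stop("out_channels must be 1, 6 or 7")
  if (any(input_shape %% 16 != 0))
    stop("input_shape must be divisible by 2^depth = 16 on every axis")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 final_activation = final_activation,
                 base_filters = as.integer(base_filters),
                 input_shape = as.integer(input_shape),
                 negative_slope = negative_slope, dropout = dropout,
                 seed = as.integer(seed)),
            class = "bs_net_config")
}

#' Build (initialize) the segmentation network
#'
#' Allocates and seeds the parameter vector: He-normal weights for
#' convolutions, zero biases, unit gains / zero shifts for instance norms.
#'
#' @param cfg A [net_config()].
#' @return A `bs_unet` model object (config + flat parameter vector).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "bs_net_config"))
  info <- cpp_unet_param_info(unclass(cfg))
  n <- sum(info$length)
  params <- numeric(n)
  with_seed(cfg$seed, {
    off <- 0L
    for (i in seq_along(info$length)) {
      len <- info$length[i]
      seg <- switch(info$type[i],
        conv = rnorm(len, 0, sqrt(2 / info$fan_in[i])),
        bias = numeric(len),
        norm = c(rep(1, len / 2), rep(0, len / 2)))
      params[(off + 1):(off + len)] <- seg
      off <- off + len
    }
  })
  structure(list(config = cfg, params = params,
                 param_info = as.data.frame(info), trained = FALSE),
            class = "bs_unet")
}

#' @export
print.bs_unet <- function(x, ...) {
  cat("<bs_unet> in=", x$config$in_channels, " out=", x$config$out_channels,
      " (", x$config$final_activation, "), base_filters=",
      x$config$base_filters, ", ", length(x$params), " parameters, ",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

# coerce network input to an (X,Y,Z,C) array
as_net_input <- function(x, in_channels) {
  d <- dim(x)
  if (length(d) == 3) {
    if (in_channels != 1) stop("model expects ", in_channels, " channels")
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4 || d[4] != in_channels) {
    stop("input must be (X,Y,Z,", in_channels, ")")
  }
  x
}

#' Forward pass: per-class probability maps
#'
#' Deterministic inference (dropout disabled). Any spatial shape divisible by
#' 16 is accepted.
#'
#' @param model `bs_unet`.
#' @param x Input array (X,Y,Z,in_channels), or (X,Y,Z) for 1 channel.
#' @return A `bs_probmaps`: scores array (X,Y,Z,C) plus activation mode.
#' @export
unet_forward <- function(model, x) {
  x <- as_net_input(x, model$config$in_channels)
  dims <- dim(x)[1:3]
  if (any(dims %% 16 != 0))
    stop("input spatial shape must be divisible by 16")
  p <- cpp_unet_forward(unclass(model$config), model$params, x,
                        as.integer(dims))
  structure(list(scores = p, mode = model$config$final_activation),
            class = "bs_probmaps")
}

#' @export
print.bs_probmaps <- function(x, ...) {
  d <- dim(x$scores)
  cat("<bs_probmaps> ", paste(d[1:3], collapse = "x"), " x ", d[4],
      " channels (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Decision rule: probabilities to labels
#'
#' Softmax mode: voxelwise argmax over the 7 channels, channel 1 being
#' background (code 0). Sigmoid mode: argmax over the 6 tissue channels, but
#' a voxel whose highest probability does not exceed 0.5 is assigned to
#' background. Exact ties go to the lowest channel index.
#'
#' @param probs `bs_probmaps` (or 4D array plus `mode`).
#' @param mode "sigmoid" or "softmax" when `probs` is a bare array.
#' @param scheme Label scheme for the output map.
#' @return `bs_labelmap` of predicted labels.
#' @export
predict_labels <- function(probs, mode = NULL, scheme = tissue_scheme()) {
  if (inherits(probs, "bs_probmaps")) {
    mode <- probs$mode
    p <- probs$scores
  } else p <- probs
  if (is.null(mode)) stop("mode must be given for a bare array")
  d <- dim(p)
  m <- matrix(p, prod(d[1:3]), d[4])
  amax <- max.col(m, ties.method = "first")
  if (mode == "softmax") {
    lab <- amax - 1L          # channel 1 is background
  } else if (d[4] == 1) {
    lab <- as.integer(m[, 1] > 0.5)
    scheme <- c(background = 0L, brain = 1L)
  } else {
    pmaxv <- m[cbind(seq_len(nrow(m)), amax)]
    lab <- ifelse(pmaxv > 0.5, amax, 0L)   # "exceeded 0.5" is strict
  }
  bs_labelmap(array(as.integer(lab), dim = d[1:3]), scheme = scheme)
}

#' Skull stripping with a binary-mode network
#'
#' Resamples the (z-scored) volume to the model's input shape, runs the
#' binary network and thresholds at 0.5, then maps the mask back to the
#' input grid by nearest-neighbour sampling.
#'
#' @param vol `bs_volume`.
#' @param model `bs_unet` built in 1-channel binary mode.
#' @return Binary `bs_labelmap` (0 background / 1 brain) on the input grid.
#' @export
skull_strip <- function(vol, model) {
  if (!inherits(model, "bs_unet") || model$config$out_channels != 1)
    stop("skull stripping requires a bs_unet in 1-channel binary mode")
  dims <- vol_dims(vol)
  target <- model$config$input_shape[1]
  z <- zscore(vol)
  cube <- resample_to_cube(z, target)
  pr <- unet_forward(model, cube$data)
  mask_cube <- array(as.integer(pr$scores[, , , 1] > 0.5), rep(target, 3))
  # back to the native grid (nearest neighbour)
  coords <- sweep(sweep(voxel_grid(dims), 2, 0.5, "+"),
                  2, target / dims, "*") - 0.5
  m <- cpp_resample(mask_cube, rep(target, 3L), coords, 0L, 0)
  bs_labelmap(array(as.integer(m), dims), affine = vol$affine,
              scheme = c(background = 0L, brain = 1L))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration, the flat parameter
#' vector and training metadata (loss, prior setting, class weights).
#'
#' @param model `bs_unet` (possibly with training metadata attached).
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly / the restored `bs_unet`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bs_unet"))
  model
}
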