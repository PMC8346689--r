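#' @keywords internal
# coerce probability/target inputs to an (nvox x C) matrix
as_prob_matrix <- function(x) {
  if (inherits(x, "bs_probmaps")) x <- x$scores
  d <- dim(x)
  if (is.null(d)) stop("probabilities must be an array or matrix")
  if (length(d) == 4) x <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  else if (length(d) != 2) stop("expected a 4D array or nvox x C matrix")
  x
}

#' Multi-label soft Dice loss
#'
#' `1 - mean_c (2 sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)` over the
#' tissue channels of a sigmoid-mode prediction; no explicit background
#' channel is involved. Bounded in \[0, 1\].
#'
#' @param probs Predicted probabilities: `bs_probmaps`, 4D array (X,Y,Z,C) or
#'   nvox x C matrix, values in \[0, 1\].
#' @param target One-hot target of the same shape.
#' @param eps Smoothing constant in numerator and denominator.
#' @param with_grad Also return the gradient with respect to `probs` (as an
#'   attribute `"gradient"`, same shape as the coerced matrix).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(probs, target, eps = 1e-5, with_grad = FALSE) {
  p <- as_prob_matrix(probs)
  t <- as_prob_matrix(target)
  if (!all(dim(p) == dim(t))) stop("probs and target shapes differ")
  C <- ncol(p)
  num <- 2 * colSums(p * t) + eps
  den <- colSums(p) + colSums(t) + eps
  loss <- 1 - mean(num / den)
  if (with_grad) {
    g <- -(sweep(2 * t, 2, den, "*") - matrix(num, nrow(p), C, byrow = TRUE)) /
      matrix(den^2, nrow(p), C, byrow = TRUE) / C
    attr(loss, "gradient") <- g
  }
  loss
}

#' Categorical cross-entropy loss
#'
#' Mean over voxels of `-sum_c t_c log p_c` for a softmax-mode prediction
#' with an explicit background channel. Probabilities are clamped at `clamp`
#' before the log.
#'
#' @inheritParams soft_dice_loss
#' @param clamp Lower clamp applied to probabilities inside the log.
#' @return Scalar loss.
#' @export
cce_loss <- function(probs, target, clamp = 1e-7, with_grad = FALSE) {
  p <- as_prob_matrix(probs)
  t <- as_prob_matrix(target)
  if (!all(dim(p) == dim(t))) stop("probs and target shapes differ")
  pc <- pmax(p, clamp)
  loss <- -sum(t * log(pc)) / nrow(p)
  if (with_grad) {
    g <- -(t / pc) / nrow(p)
    g[p < clamp & t == 0] <- 0
    attr(loss, "gradient") <- g
  }
  loss
}

#' Median-frequency class weights
#'
#' For each class `i`, `w_i = median(n_b) / median(n_i)` where `n_b` and
#' `n_i` are the per-subject voxel counts of the background and class `i`,
#' and medians are taken across the supplied label maps. The background
#' weight is 1 by construction.
#'
#' @param label_maps List of `bs_labelmap`s (or integer arrays).
#' @param scheme Label scheme; defaults to the scheme of the first map.
#' @return A named numeric vector of class `bs_class_weights`, ordered as the
#'   scheme (background first).
#' @export
median_frequency_weights <- function(label_maps, scheme = NULL) {
  if (length(label_maps) < 1) stop("need at least one label map")
  if (is.null(scheme)) {
    scheme <- if (inherits(label_maps[[1]], "bs_labelmap"))
      label_maps[[1]]$scheme else tissue_scheme()
  }
  counts <- sapply(label_maps, function(m) {
    d <- if (inherits(m, "bs_labelmap")) m$data else m
    vapply(unname(scheme), function(code) sum(d == code), numeric(1))
  })
  counts <- matrix(counts, nrow = length(scheme),
                   dimnames = list(names(scheme), NULL))
  med <- apply(counts, 1, median)
  zero <- med == 0
  if (any(zero))
    stop("median voxel count is zero for class(es): ",
         paste(names(scheme)[zero], collapse = ", "))
  w <- med[["background"]] / med
  structure(w, class = "bs_class_weights", scheme = scheme)
}

#' Median-frequency weighted categorical cross-entropy
#'
#' Mean over voxels of `-sum_c w_c t_c log p_c`. With all weights equal to 1
#' this reduces exactly to [cce_loss()].
#'
#' @inheritParams cce_loss
#' @param weights Per-channel weights, ordered like the channels of `probs`
#'   (background first in softmax mode); a `bs_class_weights` or numeric.
#' @return Scalar loss.
#' @export
wcce_loss <- function(probs, target, weights, clamp = 1e-7,
                      with_grad = FALSE) {
  p <- as_prob_matrix(probs)
  t <- as_prob_matrix(target)
  if (!all(dim(p) == dim(t))) stop("probs and target shapes differ")
  w <- as.numeric(weights)
  if (length(w) != ncol(p)) {
    present <- which(colSums(t) > 0)
    stop("need one weight per channel (", ncol(p), "); got ", length(w),
         " for channels including ", paste(present, collapse = ","))
  }
  pc <- pmax(p, clamp)
  wt <- sweep(t, 2, w, "*")
  loss <- -sum(wt * log(pc)) / nrow(p)
  if (with_grad) {
    g <- -(wt / pc) / nrow(p)
    g[p < clamp & t == 0] <- 0
    attr(loss, "gradient") <- g
  }
  loss
}

#' One-hot encode a label map
#'
#' @param labels `bs_labelmap` or integer array.
#' @param codes Channel order: vector of label codes (e.g. `1:6` for sigmoid
#'   mode, `0:6` for softmax mode).
#' @return Array (X,Y,Z,C) of 0/1.
#' @export
one_hot <- function(labels, codes) {
  d <- if (inherits(labels, "bs_labelmap")) labels$data else labels
  dims <- dim(d)
  out <- array(0, dim = c(dims, length(codes)))
  for (i in seq_along(codes)) out[, , , i] <- as.numeric(d == codes[i])
  out
}

#' Persist class weights as JSON
#'
#' @param weights `bs_class_weights`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_class_weights <- function(weights, path) {
  jsonlite::write_json(as.list(unclass(weights)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
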