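#' Crop a volume to its foreground bounding box
#'
#' Computes the tight bounding box of the foreground (nonzero intensity by
#' default, or a supplied mask), expands it by `margin` voxels, and crops the
#' volume (and optionally a label map on the same grid). The returned
#' `bs_crop_record` allows exact inversion back to the native grid with
#' [to_native()].
#'
#' @param vol A `bs_volume`.
#' @param labels Optional `bs_labelmap` on the same grid.
#' @param mask Optional logical array defining the foreground; defaults to
#'   `vol$data > 0`.
#' @param margin Margin in voxels added on every side (clipped to the grid).
#' @return List with elements `vol`, `labels` (or `NULL`) and `record`.
#' @export
crop_foreground <- function(vol, labels = NULL, mask = NULL, margin = 0L) {
  dims <- vol_dims(vol)
  if (is.null(mask)) mask <- vol$data > 0
  if (!any(mask)) stop("empty foreground: nothing to crop to")
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dims)
  cropped <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  # shift the affine origin by the 0-based crop offset
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% (lo - 1)
  out_vol <- bs_volume(cropped, affine = aff)
  out_lab <- NULL
  if (!is.null(labels)) {
    stopifnot(all(vol_dims(labels) == dims))
    out_lab <- bs_labelmap(
      labels$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
      affine = aff, scheme = labels$scheme)
  }
  record <- structure(list(
    original_shape = dims, lo = as.integer(lo), hi = as.integer(hi),
    margin = as.integer(margin), native_affine = vol$affine,
    native_spacing = vol$spacing, resample_target_shape = NULL,
    interp = c(image = "trilinear", labels = "smoothed-one-hot")),
    class = "bs_crop_record")
  list(vol = out_vol, labels = out_lab, record = record)
}

#' Uncrop a label map back onto the native grid
#'
#' Exact inverse of the cropping step (no interpolation): voxels outside the
#' crop window become background.
#'
#' @param labels `bs_labelmap` on the cropped grid.
#' @param record `bs_crop_record` from [crop_foreground()].
#' @return `bs_labelmap` on the original grid.
#' @export
uncrop_labels <- function(labels, record) {
  lo <- record$lo; hi <- record$hi
  if (!all(vol_dims(labels) == hi - lo + 1L))
    stop("label map shape does not match the crop record")
  out <- array(0L, dim = record$original_shape)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- labels$data
  bs_labelmap(out, affine = record$native_affine, scheme = labels$scheme)
}

# mapping from target-cube voxel coords (0-based) to source voxel coords:
# the cube spans the full source extent (cell-centre convention)
cube_to_source_coords <- function(src_dims, target) {
  g <- voxel_grid(rep(as.integer(target), 3L))
  sweep(sweep(g, 2, src_dims / target, "*"),
        2, 0.5 * src_dims / target - 0.5, "+")
}

#' Resample a volume or label map to an isotropic cube
#'
#' Intensities are interpolated trilinearly; label maps use the
#' smoothed-one-hot argmax rule (Gaussian-smoothed per-class indicators
#' sampled and arg-maxed), which never introduces new label codes. World
#' coordinates are preserved by updating the affine.
#'
#' @param vol `bs_volume` or `bs_labelmap`.
#' @param target Edge length of the output cube in voxels (default 128).
#' @param record Optional `bs_crop_record` to annotate with the target shape.
#' @param label_sigma Gaussian sigma (voxels) for label interpolation.
#' @return Resampled object (plus updated `record` attribute when supplied).
#' @export
resample_to_cube <- function(vol, target = 128L, record = NULL,
                             label_sigma = 0.2) {
  stopifnot(target >= 1)
  dims <- vol_dims(vol)
  coords <- cube_to_source_coords(dims, target)
  scale <- dims / target
  S <- diag(4)
  diag(S)[1:3] <- scale
  S[1:3, 4] <- 0.5 * scale - 0.5
  aff <- vol$affine %*% S
  if (inherits(vol, "bs_labelmap")) {
    lab <- cpp_warp_labels(vol$data, dims, coords, label_sigma)
    out <- bs_labelmap(array(lab, dim = rep(target, 3L)), affine = aff,
                       scheme = vol$scheme)
  } else {
    v <- cpp_resample(vol$data, dims, coords, 1L, 0)
    out <- bs_volume(array(v, dim = rep(target, 3L)), affine = aff)
  }
  if (!is.null(record)) {
    record$resample_target_shape <- rep(as.integer(target), 3L)
    attr(out, "record") <- record
  }
  out
}

#' Z-score normalize a volume
#'
#' Subtracts the mean and divides by the standard deviation over the whole
#' volume (or an optional mask region).
#'
#' @param vol `bs_volume`.
#' @param mask Optional logical array selecting the normalization region.
#' @return Normalized `bs_volume`.
#' @export
zscore <- function(vol, mask = NULL) {
  v <- if (is.null(mask)) as.vector(vol$data) else vol$data[mask]
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant volume (sd = 0)")
  bs_volume((vol$data - mean(v)) / s, affine = vol$affine)
}

#' Default random-affine augmentation parameter ranges
#'
#' @param rotation_deg Maximum rotation magnitude per axis, degrees.
#' @param scale Maximum relative scale change per axis.
#' @param translation_vox Maximum translation per axis, voxels.
#' @param shear Maximum shear coefficient.
#' @return Named list of ranges.
#' @export
augment_params <- function(rotation_deg = 10, scale = 0.1,
                           translation_vox = 5, shear = 0) {
  list(rotation_deg = rotation_deg, scale = scale,
       translation_vox = translation_vox, shear = shear)
}

# random affine voxel-space matrix (4x4) about the grid centre
random_affine_matrix <- function(dims, params) {
  ang <- runif(3, -params$rotation_deg, params$rotation_deg) * pi / 180
  sc <- 1 + runif(3, -params$scale, params$scale)
  tr <- runif(3, -params$translation_vox, params$translation_vox)
  sh <- runif(3, -params$shear, params$shear)
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% Sh %*% diag(sc)
  ctr <- (dims - 1) / 2
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- ctr - A %*% ctr + tr
  M
}

#' Random affine augmentation of an image/label pair
#'
#' Draws one random affine (bounded rotation, scale, translation, shear) and
#' applies it to the image (trilinear) and label map (smoothed-one-hot).
#'
#' @param vol `bs_volume`.
#' @param labels `bs_labelmap` on the same grid (optional).
#' @param params Ranges from [augment_params()]. Zero amplitudes give the
#'   identity transform.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param label_sigma Sigma (voxels) for label interpolation.
#' @return List with transformed `vol`, `labels` and the matrix `M`.
#' @export
random_affine_augment <- function(vol, labels = NULL,
                                  params = augment_params(), seed = 1L,
                                  label_sigma = 0.2) {
  dims <- vol_dims(vol)
  M <- with_seed(seed, random_affine_matrix(dims, params))
  Minv <- solve(M)
  coords <- apply_affine_coords(Minv, voxel_grid(dims))
  v <- cpp_resample(vol$data, dims, coords, 1L, 0)
  out_vol <- bs_volume(array(v, dim = dims), affine = vol$affine)
  out_lab <- NULL
  if (!is.null(labels)) {
    lab <- cpp_warp_labels(labels$data, dims, coords, label_sigma)
    out_lab <- bs_labelmap(array(lab, dim = dims), affine = labels$affine,
                           scheme = labels$scheme)
  }
  list(vol = out_vol, labels = out_lab, M = M)
}

#' Map a cube-grid prediction back to the native grid
#'
#' Inverts the crop + cubic-resampling geometry: every native voxel inside
#' the crop window samples the prediction with the smoothed-one-hot rule;
#' voxels outside the window are background.
#'
#' @param pred `bs_labelmap` on the resampling cube grid.
#' @param record `bs_crop_record` produced by the forward pipeline.
#' @param label_sigma Sigma (voxels) for label interpolation.
#' @return `bs_labelmap` on the native grid.
#' @export
to_native <- function(pred, record, label_sigma = 0.2) {
  if (!inherits(record, "bs_crop_record")) stop("record must be a bs_crop_record")
  target <- vol_dims(pred)
  if (length(unique(target)) != 1)
    stop("prediction must live on a cubic grid")
  target <- target[1]
  if (!is.null(record$resample_target_shape) &&
      record$resample_target_shape[1] != target)
    stop("prediction shape does not match the crop record")
  lo <- record$lo; hi <- record$hi
  crop_dims <- hi - lo + 1L
  # native voxels inside the crop window, mapped into cube coordinates
  nat <- record$original_shape
  out <- array(0L, dim = nat)
  g <- voxel_grid(crop_dims)                       # 0-based within-crop coords
  cc <- sweep(sweep(g, 2, 0.5, "+"), 2, target / crop_dims, "*") - 0.5
  lab <- cpp_warp_labels(pred$data, vol_dims(pred), cc, label_sigma)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lab
  bs_labelmap(out, affine = record$native_affine, scheme = pred$scheme)
}

#' Serialize a crop record as JSON
#'
#' Bounds are stored 0-based, half-open (`start`, `stop`), one pair per axis.
#'
#' @param record `bs_crop_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crop_record <- function(record, path) {
  obj <- list(original_shape = record$original_shape,
              crop_start = record$lo - 1L, crop_stop = record$hi,
              margin = record$margin,
              resample_target_shape = record$resample_target_shape,
              native_affine = record$native_affine,
              native_spacing = record$native_spacing,
              interp = as.list(record$interp))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a crop record from JSON
#'
#' @param path JSON file written by [write_crop_record()].
#' @return `bs_crop_record`.
#' @export
read_crop_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    original_shape = as.integer(obj$original_shape),
    lo = as.integer(obj$crop_start) + 1L, hi = as.integer(obj$crop_stop),
    margin = as.integer(obj$margin),
    native_affine = matrix(unlist(obj$native_affine), 4, 4),
    native_spacing = as.numeric(obj$native_spacing),
    resample_target_shape = if (is.null(obj$resample_target_shape)) NULL
      else as.integer(obj$resample_target_shape),
    interp = unlist(obj$interp)), class = "bs_crop_record")
}
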