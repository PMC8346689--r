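#' Registration configuration
#'
#' Controls the multi-resolution schedule of the three-stage registration.
#' All settings are deterministic: fixed initialization and fixed iteration
#' budgets, so repeated runs give identical transforms.
#'
#' @param levels Downsampling factors, coarse to fine.
#' @param rigid_iters,affine_iters Optimizer iteration budget per level.
#' @param demons_iters Demons iterations per level.
#' @param demons_step Step scale applied to the demons force.
#' @param sigma_update Gaussian sigma (voxels) smoothing each demons update.
#' @param sigma_field Gaussian sigma (voxels) smoothing the running field.
#' @return A list of settings.
#' @export
reg_config <- function(levels = c(4, 2, 1),
                       rigid_iters = c(80, 40, 0),
                       affine_iters = c(60, 40, 20),
                       demons_iters = c(40, 30, 25),
                       demons_step = 1.8,
                       sigma_update = 1.0,
                       sigma_field = 0.7) {
  list(levels = levels, rigid_iters = rigid_iters,
       affine_iters = affine_iters, demons_iters = demons_iters,
       demons_step = demons_step, sigma_update = sigma_update,
       sigma_field = sigma_field)
}

# downsample a z-scored array by integer factor f (smooth then subsample)
downsample_level <- function(arr, dims, f) {
  if (f == 1) return(list(arr = arr, dims = dims))
  dl <- pmax(as.integer(floor(dims / f)), 4L)
  sm <- cpp_gaussian_smooth(arr, dims, rep(f / 2, 3))
  g <- voxel_grid(dl)
  coords <- sweep(g * f, 2, (f - 1) / 2, "+")
  list(arr = array(cpp_resample(sm, dims, coords, 1L, 0), dim = dl), dims = dl)
}

# rigid parameters (rx, ry, rz, tx, ty, tz) -> 4x4 voxel map about centres
rigid_matrix <- function(p, ctr_s, ctr_t) {
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- ctr_t - A %*% ctr_s + p[4:6]
  M
}

# affine parameters: 9 matrix entries (row-major perturbation) + translation
affine_matrix <- function(p, ctr_s, ctr_t) {
  A <- matrix(p[1:9], 3, 3, byrow = TRUE)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- ctr_t - A %*% ctr_s + p[10:12]
  M
}

# negative NCC of template sampled at M x subject-coords vs subject
neg_ncc_objective <- function(M, sub_arr, sub_dims, tpl_arr, tpl_dims, coords) {
  cc <- apply_affine_coords(M, coords)
  w <- cpp_resample(tpl_arr, tpl_dims, cc, 1L, 0)
  -cpp_ncc(as.vector(sub_arr), w)
}

#' Three-stage registration of a subject to a template
#'
#' Fits a voxel-space transform `T(x) = A (x + d(x))` mapping subject voxel
#' coordinates to template voxel coordinates, by multi-resolution
#' maximization of normalized cross-correlation: a 6-dof rigid stage, a
#' 12-dof affine refinement, and a diffeomorphic-demons-style deformable
#' stage fitting the residual displacement field `d` on the subject grid.
#'
#' @param subject,template `bs_volume`s (consistent skull state).
#' @param stages Subset of `c("rigid", "affine", "deformable")`.
#' @param config Settings from [reg_config()].
#' @return A `bs_transform_chain` with elements `rigid`, `affine` (4x4 voxel
#'   maps), `disp` (displacement field, voxel units, or `NULL`), and the
#'   grids of both volumes.
#' @export
register <- function(subject, template,
                     stages = c("rigid", "affine", "deformable"),
                     config = reg_config()) {
  stopifnot(all(stages %in% c("rigid", "affine", "deformable")))
  sub_dims <- vol_dims(subject)
  tpl_dims <- vol_dims(template)
  szs <- sd(subject$data); szt <- sd(template$data)
  if (szs == 0 || szt == 0) stop("cannot register a constant volume")
  sub <- (subject$data - mean(subject$data)) / szs
  tpl <- (template$data - mean(template$data)) / szt
  ctr_s <- (sub_dims - 1) / 2
  ctr_t <- (tpl_dims - 1) / 2
  levels <- config$levels
  sub_l <- lapply(levels, function(f) downsample_level(sub, sub_dims, f))
  # level transforms act on full-resolution coordinates; precompute
  # coarse-grid coords expressed at full resolution
  coords_l <- lapply(seq_along(levels), function(i) {
    f <- levels[i]
    sweep(voxel_grid(sub_l[[i]]$dims) * f, 2, (f - 1) / 2, "+")
  })
  obj_level <- function(M, i) {
    neg_ncc_objective(M, sub_l[[i]]$arr, sub_l[[i]]$dims,
                      tpl, tpl_dims, coords_l[[i]])
  }
  rigid_M <- diag(4)
  rigid_M[1:3, 4] <- ctr_t - ctr_s
  p_r <- rep(0, 6)
  if ("rigid" %in% stages) {
    for (i in seq_along(levels)) {
      it <- config$rigid_iters[i]
      if (is.na(it) || it <= 0) next
      fit <- optim(p_r, function(p) obj_level(rigid_matrix(p, ctr_s, ctr_t), i),
                   method = "BFGS",
                   control = list(maxit = it, reltol = 1e-8,
                                  parscale = c(rep(0.02, 3), rep(1, 3)),
                                  ndeps = rep(1e-4, 6)))
      p_r <- fit$par
    }
    rigid_M <- rigid_matrix(p_r, ctr_s, ctr_t)
  }
  affine_M <- rigid_M
  if ("affine" %in% stages) {
    p_a <- c(as.vector(t(rigid_M[1:3, 1:3])), rigid_M[1:3, 4] -
               (ctr_t - rigid_M[1:3, 1:3] %*% ctr_s))
    for (i in seq_along(levels)) {
      it <- config$affine_iters[i]
      if (is.na(it) || it <= 0) next
      fit <- optim(p_a, function(p) obj_level(affine_matrix(p, ctr_s, ctr_t), i),
                   method = "BFGS",
                   control = list(maxit = it, reltol = 1e-8,
                                  parscale = c(rep(0.02, 9), rep(1, 3)),
                                  ndeps = rep(1e-4, 12)))
      p_a <- fit$par
    }
    affine_M <- affine_matrix(p_a, ctr_s, ctr_t)
  }
  disp <- NULL
  if ("deformable" %in% stages) {
    disp <- demons_stage(sub, sub_dims, tpl, tpl_dims, affine_M, config)
  }
  structure(list(rigid = rigid_M, affine = affine_M, disp = disp,
                 subject_dims = sub_dims, template_dims = tpl_dims,
                 subject_affine = subject$affine,
                 template_affine = template$affine,
                 subject_spacing = subject$spacing),
            class = "bs_transform_chain")
}

# demons on the residual displacement, multi-resolution (coarse to fine);
# returns list(x, y, z) arrays of full-resolution voxel displacements
demons_stage <- function(sub, sub_dims, tpl, tpl_dims, affine_M, config) {
  levels <- config$levels
  d <- NULL
  prev_f <- NA_real_
  for (i in seq_along(levels)) {
    f <- levels[i]
    sl <- downsample_level(sub, sub_dims, f)
    dl <- sl$dims
    g <- voxel_grid(dl)
    full_coords <- sweep(g * f, 2, (f - 1) / 2, "+")
    if (is.null(d)) {
      z <- array(0, dl)
      d <- list(x = z, y = z, z = z)
    } else {
      # resample the coarser field onto this level's grid; values are in
      # level-voxel units, so rescale by the factor ratio
      prev_dims <- dim(d$x)
      pc <- sweep(sweep(g, 2, 0.5, "+"), 2, prev_dims / dl, "*") - 0.5
      d <- lapply(d, function(a)
        array(cpp_resample(a, prev_dims, pc, 1L, 0) * (prev_f / f), dim = dl))
    }
    prev_f <- f
    n_it <- config$demons_iters[i]
    if (is.na(n_it) || n_it <= 0) next
    for (it in seq_len(n_it)) {
      # warped moving image: template sampled at A(x + d(x))
      cc <- cbind(full_coords[, 1] + as.vector(d$x) * f,
                  full_coords[, 2] + as.vector(d$y) * f,
                  full_coords[, 3] + as.vector(d$z) * f)
      cc <- apply_affine_coords(affine_M, cc)
      w <- array(cpp_resample(tpl, tpl_dims, cc, 1L, 0), dim = dl)
      gr <- cpp_gradient3(w, dl)
      u <- cpp_demons_force(sl$arr, w, gr$x, gr$y, gr$z)
      st <- config$demons_step
      d$x <- d$x + array(cpp_gaussian_smooth(
        array(u$x * st, dl), dl, rep(config$sigma_update, 3)), dl)
      d$y <- d$y + array(cpp_gaussian_smooth(
        array(u$y * st, dl), dl, rep(config$sigma_update, 3)), dl)
      d$z <- d$z + array(cpp_gaussian_smooth(
        array(u$z * st, dl), dl, rep(config$sigma_update, 3)), dl)
      d$x <- array(cpp_gaussian_smooth(d$x, dl, rep(config$sigma_field, 3)), dl)
      d$y <- array(cpp_gaussian_smooth(d$y, dl, rep(config$sigma_field, 3)), dl)
      d$z <- array(cpp_gaussian_smooth(d$z, dl, rep(config$sigma_field, 3)), dl)
    }
  }
  # bring the field to full resolution (displacements are in full-res voxels
  # once multiplied by the level factor)
  f_last <- levels[length(levels)]
  dl <- dim(d$x)
  if (f_last != 1 || !all(dl == sub_dims)) {
    g <- voxel_grid(sub_dims)
    pc <- sweep(sweep(g, 2, 0.5, "+"), 2, dl / sub_dims, "*") - 0.5
    d <- lapply(d, function(a)
      array(cpp_resample(a, dl, pc, 1L, 0) * f_last, dim = sub_dims))
  }
  d
}

#' Apply a transform chain to subject-grid coordinates
#'
#' @param chain `bs_transform_chain` from [register()].
#' @param coords n x 3 matrix of 0-based subject voxel coordinates (defaults
#'   to the full subject grid).
#' @return n x 3 matrix of template voxel coordinates.
#' @export
apply_chain <- function(chain, coords = NULL) {
  if (is.null(coords)) coords <- voxel_grid(chain$subject_dims)
  if (!is.null(chain$disp)) {
    dd <- dim(chain$disp$x)
    coords <- cbind(
      coords[, 1] + cpp_resample(chain$disp$x, dd, coords, 1L, 0),
      coords[, 2] + cpp_resample(chain$disp$y, dd, coords, 1L, 0),
      coords[, 3] + cpp_resample(chain$disp$z, dd, coords, 1L, 0))
  }
  apply_affine_coords(chain$affine, coords)
}

#' Mean displacement of a transform chain
#'
#' Mean Euclidean distance (voxels) between `T(x)` and `x` over the subject
#' grid; near zero for a self-registration.
#'
#' @param chain `bs_transform_chain`.
#' @return Scalar mean displacement in voxels.
#' @export
mean_displacement <- function(chain) {
  g <- voxel_grid(chain$subject_dims)
  tc <- apply_chain(chain, g)
  mean(sqrt(rowSums((tc - g)^2)))
}

#' Invert a displacement field by fixed-point iteration
#'
#' @param disp List of arrays `x`, `y`, `z` (voxel displacements).
#' @param iters Fixed-point iterations.
#' @return Displacement field of the inverse map on the same grid.
#' @export
invert_displacement <- function(disp, iters = 20L) {
  dims <- dim(disp$x)
  g <- voxel_grid(dims)
  inv <- list(x = array(0, dims), y = array(0, dims), z = array(0, dims))
  for (i in seq_len(iters)) {
    cc <- cbind(g[, 1] + as.vector(inv$x), g[, 2] + as.vector(inv$y),
                g[, 3] + as.vector(inv$z))
    inv <- list(
      x = array(-cpp_resample(disp$x, dims, cc, 1L, 0), dims),
      y = array(-cpp_resample(disp$y, dims, cc, 1L, 0), dims),
      z = array(-cpp_resample(disp$z, dims, cc, 1L, 0), dims))
  }
  inv
}

#' Warp template labels into subject space (spatial prior)
#'
#' Each class indicator (including background) is smoothed with a Gaussian of
#' `sigma_vox` voxels, pulled through the fitted transform, and the voxelwise
#' argmax over classes gives the integer prior on the subject grid.
#'
#' @param template_labels `bs_labelmap` on the template grid.
#' @param chain `bs_transform_chain` from [register()].
#' @param sigma_vox Label-interpolation sigma in voxels (default 0.2).
#' @param coords Optional n x 3 subject voxel coordinates (defaults to the
#'   full subject grid); used to compose with preprocessing geometry.
#' @param out_dims Grid dims of the output when `coords` is supplied.
#' @return `bs_labelmap` prior on the subject grid.
#' @export
warp_labels <- function(template_labels, chain, sigma_vox = 0.2,
                        coords = NULL, out_dims = NULL) {
  if (sigma_vox < 0) stop("sigma_vox must be >= 0")
  if (is.null(out_dims)) out_dims <- chain$subject_dims
  tc <- apply_chain(chain, coords)
  lab <- cpp_warp_labels(template_labels$data, vol_dims(template_labels),
                         tc, sigma_vox)
  bs_labelmap(array(lab, dim = out_dims), affine = chain$subject_affine,
              scheme = template_labels$scheme)
}

#' Build a patient-specific spatial prior
#'
#' Convenience wrapper: three-stage registration of the subject to the
#' template followed by label propagation with [warp_labels()]. The result
#' doubles as the "registration to atlas" baseline segmentation.
#'
#' @param subject_t1 `bs_volume`.
#' @param template_t1 `bs_volume`.
#' @param template_labels `bs_labelmap`.
#' @param config [reg_config()].
#' @param sigma_vox Label-interpolation sigma.
#' @param stages Registration stages to run.
#' @return `bs_labelmap` prior with the fitted chain in attribute `chain`.
#' @export
build_prior <- function(subject_t1, template_t1, template_labels,
                        config = reg_config(), sigma_vox = 0.2,
                        stages = c("rigid", "affine", "deformable")) {
  chain <- register(subject_t1, template_t1, stages = stages, config = config)
  prior <- warp_labels(template_labels, chain, sigma_vox = sigma_vox)
  attr(prior, "chain") <- chain
  prior
}
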