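#' Specification of a synthetic brain phantom
#'
#' Defines the geometry, intensity model and variability of the synthetic
#' T1-like phantoms: six concentric/segregated tissue compartments (CSF shell
#' plus ventricles, a thin cortical gray matter shell, white matter interior,
#' paired deep gray matter nuclei, an inferior brainstem cylinder and a
#' posterior cerebellum lobe), a smooth multiplicative bias field, additive
#' noise, per-subject smooth random warps and T1-hypointense lesions.
#'
#' `contrast_scale` multiplies the deep-gray-vs-white-matter intensity gap:
#' at 1 the deep gray nuclei have their full nominal contrast, at 0 they are
#' isointense to white matter (the hard, low-contrast regime).
#'
#' @param grid_shape Voxels per axis (>= 32 each).
#' @param spacing_mm Voxel size in mm per axis.
#' @param tissue_means Named mean intensity per class (csf, cortical_gm, wm,
#'   deep_gm, brainstem, cerebellum); `deep_gm` is the full-contrast value.
#' @param tissue_sds Between-subject SD of each class mean.
#' @param contrast_scale Scalar in \[0, 1\], see above.
#' @param bias_amplitude Relative amplitude of the multiplicative bias field.
#' @param noise_sd Additive voxel noise SD.
#' @param deform_sd_mm RMS magnitude of the per-subject random warp, mm.
#' @param deform_smooth_mm Gaussian smoothness of the warp, mm.
#' @param lesion_count Number of lesions per subject.
#' @param lesion_radius_range_mm Min/max lesion radius, mm.
#' @param lesion_intensity_shift Additive intensity shift inside lesions
#'   (negative = T1-hypointense).
#' @param lesion_tissue One of "WM", "GM", "mixed".
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return A `bs_phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(3, 3, 3),
                         tissue_means = c(csf = 20, cortical_gm = 60, wm = 100,
                                          deep_gm = 70, brainstem = 85,
                                          cerebellum = 65),
                         tissue_sds = c(csf = 2, cortical_gm = 3, wm = 3,
                                        deep_gm = 3, brainstem = 3,
                                        cerebellum = 3),
                         contrast_scale = 0.5,
                         bias_amplitude = 0.1,
                         noise_sd = 4,
                         deform_sd_mm = 4,
                         deform_smooth_mm = 12,
                         lesion_count = 2,
                         lesion_radius_range_mm = c(6, 12),
                         lesion_intensity_shift = -30,
                         lesion_tissue = c("WM", "GM", "mixed"),
                         seed = 1L) {
  lesion_tissue <- match.arg(lesion_tissue)
  stopifnot(length(grid_shape) == 3, length(spacing_mm) == 3,
            contrast_scale >= 0, contrast_scale <= 1,
            lesion_count >= 0, length(lesion_radius_range_mm) == 2)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 tissue_means = tissue_means, tissue_sds = tissue_sds,
                 contrast_scale = contrast_scale,
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 deform_sd_mm = deform_sd_mm,
                 deform_smooth_mm = deform_smooth_mm,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_range_mm = lesion_radius_range_mm,
                 lesion_intensity_shift = lesion_intensity_shift,
                 lesion_tissue = lesion_tissue, seed = as.integer(seed)),
            class = "bs_phantom_spec")
}

# class means with the deep-gray contrast dialled by contrast_scale
effective_means <- function(means, contrast_scale) {
  means["deep_gm"] <- means["wm"] - contrast_scale * (means["wm"] - means["deep_gm"])
  means
}

# squared elliptical radius field for centre ctr (voxels) and semi-axes rad
ellipsoid_field <- function(dims, ctr, rad) {
  x <- ((seq_len(dims[1]) - 1) - ctr[1]) / rad[1]
  y <- ((seq_len(dims[2]) - 1) - ctr[2]) / rad[2]
  z <- ((seq_len(dims[3]) - 1) - ctr[3]) / rad[3]
  outer(outer(x^2, y^2, "+"), z^2, "+")
}

# canonical template label geometry
template_labels_array <- function(dims) {
  ctr <- (dims - 1) / 2
  R <- 0.40 * dims
  re2 <- ellipsoid_field(dims, ctr, R)
  lab <- array(0L, dim = dims)
  lab[re2 <= 1] <- 1L                                   # CSF outer shell
  lab[re2 <= 0.94^2] <- 2L                              # cortical GM shell
  lab[re2 <= 0.82^2] <- 3L                              # WM interior
  # lateral ventricles (CSF)
  for (s in c(-1, 1)) {
    v <- ellipsoid_field(dims, ctr + c(s * 0.11 * R[1], 0, 0),
                         c(0.09, 0.22, 0.16) * R)
    lab[v <= 1 & lab == 3L] <- 1L
  }
  # deep gray nuclei lateral to the ventricles; sized so deep gray is
  # roughly 3% of the brain, as in adult anatomy
  for (s in c(-1, 1)) {
    v <- ellipsoid_field(dims, ctr + c(s * 0.36 * R[1], -0.05 * R[2], 0),
                         c(0.19, 0.26, 0.22) * R)
    lab[v <= 1 & lab == 3L] <- 4L
  }
  # posterior-inferior cerebellum lobe
  cb <- ellipsoid_field(dims, ctr + c(0, 0.38 * R[2], -0.42 * R[3]),
                        c(0.46, 0.32, 0.28) * R)
  lab[cb <= 1] <- 6L
  # inferior brainstem cylinder (overrides everything it meets)
  xg <- (seq_len(dims[1]) - 1) - ctr[1]
  yg <- (seq_len(dims[2]) - 1) - ctr[2]
  r2 <- outer(xg^2, yg^2, "+") / (0.15 * R[1])^2
  zr <- (seq_len(dims[3]) - 1)
  zmask <- zr >= ctr[3] - 0.95 * R[3] & zr <= ctr[3] - 0.20 * R[3]
  cyl <- array(FALSE, dims)
  cyl[, , zmask] <- rep(r2 <= 1, sum(zmask))
  lab[cyl] <- 5L
  lab
}

# smooth standardized random field (sigma in voxels)
smooth_noise_field <- function(dims, sigma_vox) {
  f <- cpp_gaussian_smooth(array(rnorm(prod(dims)), dim = dims), dims,
                           rep(sigma_vox, 3))
  s <- sd(f)
  if (s == 0) return(array(0, dims))
  array((f - mean(f)) / s, dim = dims)
}

# low-order polynomial log-bias field, unit-SD before scaling
polynomial_bias_field <- function(dims) {
  t1 <- seq(-1, 1, length.out = dims[1])
  t2 <- seq(-1, 1, length.out = dims[2])
  t3 <- seq(-1, 1, length.out = dims[3])
  f <- array(0, dims)
  for (a in 0:2) for (b in 0:2) for (cdeg in 0:2) {
    d <- a + b + cdeg
    if (d == 0 || d > 2) next
    f <- f + rnorm(1) * outer(outer(t1^a, t2^b), t3^cdeg)
  }
  array((f - mean(f)) / sd(f), dim = dims)
}

#' Generate the canonical template phantom
#'
#' Returns the undeformed, lesion-free, bias-free phantom used as the
#' registration template: nested ellipsoidal CSF / cortical GM / WM shells
#' with ventricles, deep gray nuclei, a brainstem cylinder and a cerebellum
#' lobe. The image is the per-class mean intensity map lightly smoothed to
#' create boundary gradients.
#'
#' @param spec A [phantom_spec()].
#' @return List with `vol` (`bs_volume`) and `labels` (`bs_labelmap`).
#' @export
make_template <- function(spec) {
  dims <- spec$grid_shape
  if (any(dims < 32))
    stop("grid too small: all six compartments need >= 32 voxels per axis")
  lab <- template_labels_array(dims)
  means <- effective_means(spec$tissue_means, spec$contrast_scale)
  img <- array(c(0, unname(means))[lab + 1L], dim = dims)
  img <- cpp_gaussian_smooth(img, dims, rep(0.7, 3))
  img[lab == 0L] <- 0
  aff <- diag(c(spec$spacing_mm, 1))
  list(vol = bs_volume(array(img, dims), affine = aff),
       labels = bs_labelmap(lab, affine = aff))
}

# draw a random smooth displacement field (voxel units), RMS magnitude
# deform_sd_mm, smoothness deform_smooth_mm
random_warp <- function(dims, spacing, sd_mm, smooth_mm) {
  if (sd_mm <= 0) {
    z <- array(0, dims)
    return(list(x = z, y = z, z = z))
  }
  sig <- smooth_mm / spacing
  d <- lapply(1:3, function(a)
    cpp_gaussian_smooth(array(rnorm(prod(dims)), dim = dims), dims, sig))
  rms <- sqrt(mean(d[[1]]^2 + d[[2]]^2 + d[[3]]^2))
  sc <- (sd_mm / mean(spacing)) / rms
  list(x = d[[1]] * sc, y = d[[2]] * sc, z = d[[3]] * sc)
}

# place one roughly spherical lesion inside `class_mask`; returns logical
# array or NULL if no fit was found after `attempts` tries
place_lesion <- function(class_mask, dims, spacing, r_mm, attempts = 100L) {
  cand <- which(class_mask)
  if (length(cand) == 0) return(NULL)
  rough <- smooth_noise_field(dims, 2) * 0.2
  for (i in seq_len(attempts)) {
    ctr_idx <- cand[sample.int(length(cand), 1)]
    ctr <- arrayInd(ctr_idx, dims)[1, ] - 1
    x <- ((seq_len(dims[1]) - 1) - ctr[1]) * spacing[1]
    y <- ((seq_len(dims[2]) - 1) - ctr[2]) * spacing[2]
    z <- ((seq_len(dims[3]) - 1) - ctr[3]) * spacing[3]
    d2 <- ellipsoid_field(dims, ctr, r_mm / spacing)
    if (any(d2 <= 1 & !class_mask)) next      # sphere must fit inside tissue
    # the perturbed boundary is intersected with the tissue mask below, so
    # the subset invariant holds by construction
    dist2 <- ellipsoid_field(dims, ctr, r_mm / spacing)
    lesion <- dist2 <= (1 + rough)^2 & class_mask
    if (sum(lesion) >= 2) return(lesion)
  }
  NULL
}

#' Sample a subject phantom from a template
#'
#' Applies a random smooth warp to the template image and labels, re-draws
#' per-tissue mean intensities, inserts hypo-/hyper-intense lesions into the
#' requested tissue (ground-truth labels keep the underlying tissue class),
#' and adds a multiplicative bias field and voxel noise.
#'
#' @param template List from [make_template()].
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for this subject.
#' @return List with `vol`, `labels`, `lesions` (list of logical arrays `gm`,
#'   `wm`), and `warp` (the displacement field, voxel units).
#' @export
sample_subject <- function(template, spec, seed = spec$seed) {
  dims <- spec$grid_shape
  with_seed(seed, {
    warp <- random_warp(dims, spec$spacing_mm, spec$deform_sd_mm,
                        spec$deform_smooth_mm)
    g <- voxel_grid(dims)
    coords <- cbind(g[, 1] + as.vector(warp$x),
                    g[, 2] + as.vector(warp$y),
                    g[, 3] + as.vector(warp$z))
    lab <- array(cpp_warp_labels(template$labels$data, dims, coords, 0.2),
                 dim = dims)
    means <- spec$tissue_means + rnorm(6) * spec$tissue_sds
    names(means) <- names(spec$tissue_means)
    means <- effective_means(means, spec$contrast_scale)
    img <- array(c(0, unname(means))[lab + 1L], dim = dims)
    img <- cpp_gaussian_smooth(img, dims, rep(0.7, 3))
    img[lab == 0L] <- 0
    # lesions: intensity shift applied before bias and noise
    gm_lesion <- array(FALSE, dims)
    wm_lesion <- array(FALSE, dims)
    if (spec$lesion_count > 0) {
      tissues <- switch(spec$lesion_tissue,
                        WM = rep("WM", spec$lesion_count),
                        GM = rep("GM", spec$lesion_count),
                        mixed = rep(c("WM", "GM"),
                                    length.out = spec$lesion_count))
      for (tt in tissues) {
        class_mask <- if (tt == "WM") lab == 3L else lab == 2L | lab == 4L
        r_mm <- runif(1, spec$lesion_radius_range_mm[1],
                      spec$lesion_radius_range_mm[2])
        les <- place_lesion(class_mask, dims, spec$spacing_mm, r_mm)
        if (is.null(les))
          stop("could not place a ", tt,
               " lesion inside the target tissue after 100 attempts")
        img[les] <- img[les] + spec$lesion_intensity_shift
        if (tt == "WM") wm_lesion <- wm_lesion | les
        else gm_lesion <- gm_lesion | les
      }
    }
    if (spec$bias_amplitude > 0) {
      bias <- exp(spec$bias_amplitude * polynomial_bias_field(dims))
      img <- img * bias
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
    img[lab == 0L & img < 0] <- 0
    aff <- diag(c(spec$spacing_mm, 1))
    list(vol = bs_volume(array(img, dims), affine = aff),
         labels = bs_labelmap(lab, affine = aff),
         lesions = list(gm = gm_lesion, wm = wm_lesion),
         warp = warp)
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` subject phantoms (T1, ground-truth labels, lesion masks) plus
#' the template as NIfTI files, together with a CSV manifest recording paths,
#' lesion summaries and a seeded train/val/test split.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of subjects (>= 1).
#' @param seed Cohort seed (subject seeds are derived from it).
#' @param dir Output directory.
#' @param fractions Train/val/test fractions (must sum to 1).
#' @param overwrite Overwrite an existing directory?
#' @return List with `manifest` (data.frame), `template` paths and `dir`.
#' @export
make_cohort <- function(spec, n, seed = 1L, dir,
                        fractions = c(0.8, 0.1, 0.1), overwrite = FALSE) {
  stopifnot(n >= 1, abs(sum(fractions) - 1) < 1e-8)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("output directory ", dir, " exists; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- make_template(spec)
  tpl_t1 <- file.path(dir, "template_T1.nii.gz")
  tpl_lab <- file.path(dir, "template_labels.nii.gz")
  write_volume(tpl$vol, tpl_t1)
  write_labelmap(tpl$labels, tpl_lab)
  sizes <- diff(floor(cumsum(c(0, fractions)) * n + 1e-9))
  sizes[1] <- n - sum(sizes[-1])
  split <- rep(c("train", "val", "test"), times = sizes)
  ord <- with_seed(seed, sample.int(n))
  split <- split[order(ord)]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%03d", i)
    subj <- sample_subject(tpl, spec, seed = seed * 1000L + i)
    p_t1 <- file.path(dir, paste0(sid, "_T1.nii.gz"))
    p_lab <- file.path(dir, paste0(sid, "_labels.nii.gz"))
    p_gm <- file.path(dir, paste0(sid, "_gmlesion.nii.gz"))
    p_wm <- file.path(dir, paste0(sid, "_wmlesion.nii.gz"))
    write_volume(subj$vol, p_t1)
    write_labelmap(subj$labels, p_lab)
    write_labelmap(bs_labelmap(array(as.integer(subj$lesions$gm),
                                     spec$grid_shape),
                               affine = subj$labels$affine,
                               scheme = c(background = 0L, lesion = 1L)), p_gm)
    write_labelmap(bs_labelmap(array(as.integer(subj$lesions$wm),
                                     spec$grid_shape),
                               affine = subj$labels$affine,
                               scheme = c(background = 0L, lesion = 1L)), p_wm)
    rows[[i]] <- data.frame(
      subject = sid, t1 = p_t1, labels = p_lab,
      gm_lesion = p_gm, wm_lesion = p_wm,
      n_gm_lesion_vox = sum(subj$lesions$gm),
      n_wm_lesion_vox = sum(subj$lesions$wm),
      lesion_tissue = spec$lesion_tissue, split = split[i],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, template = list(t1 = tpl_t1, labels = tpl_lab),
       dir = dir)
}
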