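#' Tissue label scheme
#'
#' The label coding used throughout the package: 0 background, 1
#' cerebrospinal fluid, 2 cortical gray matter, 3 white matter, 4 deep gray
#' matter, 5 brainstem, 6 cerebellum.
#'
#' @return Named integer vector mapping tissue names to label codes.
#' @export
tissue_scheme <- function() {
  c(background = 0L, csf = 1L, cortical_gm = 2L, wm = 3L,
    deep_gm = 4L, brainstem = 5L, cerebellum = 6L)
}

#' MRBrainS18-style external label scheme
#'
#' The 10-class manual scheme of the external data set: 1 CSF, 2 basal
#' ganglia, 3 white matter, 4 white matter hyperintensity, 5 cortical gray
#' matter, 6 ventricles, 7 cerebellum, 8 brainstem, 9 infarction, 10 other.
#'
#' @return Named integer vector.
#' @export
external_scheme <- function() {
  c(background = 0L, csf = 1L, basal_ganglia = 2L, wm = 3L, wmh = 4L,
    cortical_gm = 5L, ventricles = 6L, cerebellum = 7L, brainstem = 8L,
    infarction = 9L, other = 10L)
}

#' Construct a scalar volume
#'
#' A `bs_volume` holds a 3D scalar array together with its voxel-to-world
#' affine (0-based voxel indices) and voxel spacing in mm.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)`.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return A `bs_volume` object.
#' @export
bs_volume <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("volume data must be finite everywhere")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(data = data, affine = affine, spacing = as.numeric(spacing)),
            class = "bs_volume")
}

#' Construct an integer label map
#'
#' @param data 3D integer array with values drawn from `scheme`.
#' @param affine 4x4 voxel-to-world matrix.
#' @param spacing Voxel size in mm.
#' @param scheme Named integer vector of legal label codes.
#' @return A `bs_labelmap` object.
#' @export
bs_labelmap <- function(data, affine = NULL, spacing = c(1, 1, 1),
                        scheme = tissue_scheme()) {
  stopifnot(length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), unname(scheme))
  if (length(bad) > 0)
    stop("label map contains codes not in scheme: ", paste(bad, collapse = ", "))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(data = data, affine = affine, spacing = as.numeric(spacing),
                 scheme = scheme),
            class = "bs_labelmap")
}

#' @export
print.bs_volume <- function(x, ...) {
  cat("<bs_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.bs_labelmap <- function(x, ...) {
  tab <- table(factor(x$data, levels = unname(x$scheme),
                      labels = names(x$scheme)))
  cat("<bs_labelmap> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  print(tab)
  invisible(x)
}

vol_dims <- function(x) dim(x$data)

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `bs_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  bs_volume(array(as.numeric(img), dim = dim(img)), affine = unclass(aff))
}

#' Read a NIfTI label map
#'
#' @inheritParams read_volume
#' @param scheme Label scheme the codes must belong to.
#' @return A `bs_labelmap`.
#' @export
read_labelmap <- function(path, scheme = tissue_scheme()) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  bs_labelmap(array(as.integer(round(as.numeric(img))), dim = dim(img)),
              affine = unclass(aff), scheme = scheme)
}

#' Write a volume or label map as NIfTI
#'
#' @param x A `bs_volume` or `bs_labelmap`.
#' @param path Output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- x$data
  if (inherits(x, "bs_labelmap")) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_labelmap <- write_volume

# 0-based voxel coordinate grid (n x 3, x fastest), matching array layout
voxel_grid <- function(dims) {
  cbind(rep.int(seq_len(dims[1]) - 1, dims[2] * dims[3]),
        rep.int(rep(seq_len(dims[2]) - 1, each = dims[1]), dims[3]),
        rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]))
}

# apply a 4x4 (or 3x4) matrix to n x 3 coordinates
apply_affine_coords <- function(M, coords) {
  out <- coords %*% t(M[1:3, 1:3])
  out[, 1] <- out[, 1] + M[1, 4]
  out[, 2] <- out[, 2] + M[2, 4]
  out[, 3] <- out[, 3] + M[3, 4]
  out
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
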