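label_data <- function(x) if (inherits(x, "bs_labelmap")) x$data else x

#' Dice overlap of one class
#'
#' `D = 2TP / (2TP + FP + FN)` from voxel confusion counts of the binarized
#' class. If both masks are empty the Dice is 1 by convention.
#'
#' @param pred,truth Label maps (`bs_labelmap` or integer arrays) on the
#'   same grid.
#' @param class Label code to evaluate.
#' @param ignore Optional logical array of voxels excluded from the counts.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(pred, truth, class, ignore = NULL) {
  p <- label_data(pred) == class
  t <- label_data(truth) == class
  if (!all(dim(p) == dim(t))) stop("pred and truth grids differ")
  if (!is.null(ignore)) {
    p <- p & !ignore
    t <- t & !ignore
  }
  tp <- sum(p & t)
  denom <- 2 * tp + sum(p & !t) + sum(!p & t)
  if (denom == 0) return(1.0)
  2 * tp / denom
}

#' Volume similarity of one class
#'
#' `VS = 1 - |V_X - V_Y| / (V_X + V_Y)`; purely volume-based (blind to
#' location). Returns 1 when both volumes are zero.
#'
#' @inheritParams dice
#' @return Scalar in \[0, 1\].
#' @export
volume_similarity <- function(pred, truth, class, ignore = NULL) {
  p <- label_data(pred) == class
  t <- label_data(truth) == class
  if (!all(dim(p) == dim(t))) stop("pred and truth grids differ")
  if (!is.null(ignore)) {
    p <- p & !ignore
    t <- t & !ignore
  }
  vx <- sum(p); vy <- sum(t)
  if (vx + vy == 0) return(1.0)
  1 - abs(vx - vy) / (vx + vy)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Directed by default, exactly as defined: the 95th percentile of the
#' minimum Euclidean distances from every predicted voxel of the class to
#' the true voxel set, honoring anisotropic spacing. The percentile uses
#' linear interpolation between order statistics (R quantile type 7). With
#' `symmetric = TRUE` the maximum of the two directed values is returned.
#' Returns `NaN` if either mask is empty.
#'
#' @inheritParams dice
#' @param spacing Voxel spacing in mm (length 3); taken from `truth` if it
#'   is a `bs_labelmap`.
#' @param symmetric Use the symmetric variant?
#' @return Distance in mm.
#' @export
hd95 <- function(pred, truth, class, spacing = NULL, symmetric = FALSE) {
  if (is.null(spacing)) {
    spacing <- if (inherits(truth, "bs_labelmap")) truth$spacing else c(1, 1, 1)
  }
  p <- label_data(pred) == class
  t <- label_data(truth) == class
  if (!all(dim(p) == dim(t))) stop("pred and truth grids differ")
  if (!any(p) || !any(t)) return(NaN)
  dims <- dim(p)
  directed <- function(a, b) {
    # min distance from every voxel of a to the set b
    d2 <- cpp_sq_edt(array(as.integer(b), dims), dims, spacing)
    unname(quantile(sqrt(d2[a]), 0.95, type = 7))
  }
  d <- directed(p, t)
  if (symmetric) d <- max(d, directed(t, p))
  d
}

#' Intra-lesion tissue classification accuracy
#'
#' Proportion of white-matter-lesion voxels predicted as white matter (label
#' 3), and of gray-matter-lesion voxels predicted as cortical (2) or deep
#' (4) gray matter. An empty mask yields `NA` (excluded from cohort
#' aggregates).
#'
#' @param pred Predicted label map.
#' @param gm_lesion,wm_lesion Logical arrays on the prediction grid.
#' @return Named list `acc_gm`, `acc_wm`.
#' @export
intra_lesion_accuracy <- function(pred, gm_lesion = NULL, wm_lesion = NULL) {
  p <- label_data(pred)
  acc <- function(mask, ok_codes) {
    if (is.null(mask) || sum(mask) == 0) return(NA_real_)
    sum(p[mask] %in% ok_codes) / sum(mask)
  }
  list(acc_gm = acc(gm_lesion, c(2L, 4L)), acc_wm = acc(wm_lesion, 3L))
}

#' Two-sample Z comparison
#'
#' `Z = (xbar1 - xbar2) / sqrt(s1^2/n1 + s2^2/n2)` with sample means and
#' standard deviations; `|Z| > 2.5` flags a significant difference (Z > 2.5:
#' group 1 higher; Z < -2.5: group 1 lower). Zero variance in both samples
#' gives Z = 0 for equal means and signed infinity (flagged) otherwise.
#'
#' @param sample1,sample2 Numeric vectors (n >= 2 each).
#' @return A `bs_zcomparison` list: means, SDs, sizes, `z`, `significant`,
#'   `direction`.
#' @export
z_compare <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2)
    stop("both samples need n >= 2")
  z_from_summary(mean(sample1), sd(sample1), length(sample1),
                 mean(sample2), sd(sample2), length(sample2))
}

#' @rdname z_compare
#' @param m1,s1,n1,m2,s2,n2 Summary statistics of the two samples.
#' @export
z_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  se <- sqrt(s1^2 / n1 + s2^2 / n2)
  z <- if (se == 0) {
    if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else (m1 - m2) / se
  structure(list(mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2, n1 = n1,
                 n2 = n2, z = z, significant = abs(z) > 2.5,
                 direction = if (z > 2.5) "group1_higher"
                             else if (z < -2.5) "group1_lower"
                             else "not_significant"),
            class = "bs_zcomparison")
}

#' @export
print.bs_zcomparison <- function(x, ...) {
  cat(sprintf("Z = %.3f (%s): %.4f+/-%.4f (n=%d) vs %.4f+/-%.4f (n=%d)\n",
              x$z, x$direction, x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  invisible(x)
}

#' Evaluate a cohort of predictions
#'
#' Per-subject, per-tissue Dice, volume similarity and HD95, cohort mean and
#' SD per tissue plus the overall (across-tissue) mean per subject, and —
#' when lesion masks are supplied — per-subject intra-lesion accuracies with
#' cohort mean, median and IQR.
#'
#' @param preds,truths Matched lists of label maps.
#' @param scheme Label scheme; metrics cover every non-background class.
#' @param lesion_masks Optional list (one per subject) of lists with `gm`
#'   and `wm` logical arrays.
#' @param spacing Spacing for HD95 (defaults per subject from truths).
#' @param ignore Optional list of logical exclusion masks per subject.
#' @return A `bs_metrics_report`: `per_subject` (long data.frame), `summary`
#'   (per-tissue), `overall`, `intra_lesion` (or NULL).
#' @export
evaluate_cohort <- function(preds, truths, scheme = tissue_scheme(),
                            lesion_masks = NULL, spacing = NULL,
                            ignore = NULL) {
  if (length(preds) != length(truths))
    stop("preds and truths must have matching lengths")
  classes <- scheme[scheme != 0 & names(scheme) != "excluded"]
  rows <- list()
  for (i in seq_along(preds)) {
    ig <- if (is.null(ignore)) NULL else ignore[[i]]
    for (ci in seq_along(classes)) {
      code <- unname(classes[ci])
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, class = names(classes)[ci], code = code,
        dice = dice(preds[[i]], truths[[i]], code, ignore = ig),
        vs = volume_similarity(preds[[i]], truths[[i]], code, ignore = ig),
        hd95_mm = hd95(preds[[i]], truths[[i]], code,
                       spacing = if (is.null(spacing)) NULL else spacing))
    }
  }
  per_subject <- do.call(rbind, rows)
  agg <- function(metric) {
    m <- tapply(per_subject[[metric]], per_subject$class, mean, na.rm = TRUE)
    s <- tapply(per_subject[[metric]], per_subject$class, sd, na.rm = TRUE)
    data.frame(class = names(m), mean = as.numeric(m), sd = as.numeric(s))
  }
  summary_df <- data.frame(
    class = agg("dice")$class,
    dice_mean = agg("dice")$mean, dice_sd = agg("dice")$sd,
    vs_mean = agg("vs")$mean, vs_sd = agg("vs")$sd,
    hd95_mean = agg("hd95_mm")$mean, hd95_sd = agg("hd95_mm")$sd)
  # overall = per-subject mean across tissues, then cohort mean +/- SD
  subj_means <- tapply(per_subject$dice, per_subject$subject, mean)
  overall <- list(dice_mean = mean(subj_means),
                  dice_sd = if (length(subj_means) > 1) sd(subj_means) else 0,
                  per_subject = as.numeric(subj_means))
  intra <- NULL
  if (!is.null(lesion_masks)) {
    accs <- lapply(seq_along(preds), function(i)
      intra_lesion_accuracy(preds[[i]], lesion_masks[[i]]$gm,
                            lesion_masks[[i]]$wm))
    gm <- vapply(accs, function(a) a$acc_gm, numeric(1))
    wm <- vapply(accs, function(a) a$acc_wm, numeric(1))
    iqr3 <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(c(NA, NA, NA, NA))
      c(mean(v), unname(quantile(v, c(0.5, 0.25, 0.75))))
    }
    g <- iqr3(gm); w <- iqr3(wm)
    intra <- list(per_subject = data.frame(subject = seq_along(preds),
                                           acc_gm = gm, acc_wm = wm),
                  gm = list(mean = g[1], median = g[2], q1 = g[3], q3 = g[4]),
                  wm = list(mean = w[1], median = w[2], q1 = w[3], q3 = w[4]))
  }
  structure(list(per_subject = per_subject, summary = summary_df,
                 overall = overall, intra_lesion = intra),
            class = "bs_metrics_report")
}

#' @export
print.bs_metrics_report <- function(x, ...) {
  cat("<bs_metrics_report>\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat(sprintf("overall Dice %.3f +/- %.3f (n=%d)\n", x$overall$dice_mean,
              x$overall$dice_sd, length(x$overall$per_subject)))
  invisible(x)
}

#' Harmonize an external 10-class label map to the internal scheme
#'
#' Ventricles and CSF are condensed into CSF (1); white matter
#' hyperintensities become white matter (3); basal ganglia map to deep gray
#' matter (4); cortical gray matter to 2, cerebellum to 6, brainstem to 5.
#' Infarction and "other" are unclassifiable as gray or white matter and
#' receive the excluded code 255, which must be masked out of all metric
#' computations (see [excluded_mask()]).
#'
#' @param ext `bs_labelmap` using [external_scheme()] codes.
#' @return `bs_labelmap` in the internal scheme (plus `excluded = 255`).
#' @export
harmonize_external_labels <- function(ext) {
  d <- label_data(ext)
  known <- c(0:10)
  bad <- setdiff(unique(as.vector(d)), known)
  if (length(bad) > 0)
    stop("unknown external label code(s): ", paste(bad, collapse = ", "))
  # external: 1 CSF, 2 basal ganglia, 3 WM, 4 WMH, 5 cortical GM,
  #           6 ventricles, 7 cerebellum, 8 brainstem, 9 infarct, 10 other
  lut <- c(0L, 1L, 4L, 3L, 3L, 2L, 1L, 6L, 5L, 255L, 255L)
  out <- array(lut[d + 1L], dim = dim(d))
  scheme <- c(tissue_scheme(), excluded = 255L)
  bs_labelmap(out, affine = if (inherits(ext, "bs_labelmap")) ext$affine
              else NULL, scheme = scheme)
}

#' Excluded-voxel mask of a harmonized label map
#'
#' @param labels `bs_labelmap` from [harmonize_external_labels()].
#' @return Logical array, TRUE where voxels must be excluded from metrics.
#' @export
excluded_mask <- function(labels) {
  label_data(labels) == 255L
}

#' Write a metrics report to CSV + JSON
#'
#' @param report `bs_metrics_report`.
#' @param csv_path Per-subject long-format CSV path.
#' @param json_path Summary JSON path.
#' @return Invisibly, the two paths.
#' @export
write_metrics_report <- function(report, csv_path, json_path) {
  write.csv(report$per_subject, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, overall = report$overall[c("dice_mean",
                                                              "dice_sd")],
         intra_lesion = report$intra_lesion[c("gm", "wm")]),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv_path, json_path))
}
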