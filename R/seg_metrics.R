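# Segmentation evaluation: voxel-overlap metrics (Dice, precision, recall)
# and physical surface distances (Hausdorff, average symmetric surface
# distance). Distances are always in mm -- clinical slices are anisotropic
# (e.g. 5 mm thick), so index-space distances would be wrong.

#' Voxelwise confusion counts
#'
#' @param pred,truth [binary_mask()]s on the same grid.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "binary_mask"), inherits(truth, "binary_mask"))
  check_same_grid(dim(pred$labels), pred$spacing,
                  dim(truth$labels), truth$spacing)
  p <- pred$labels == 1L
  t <- truth$labels == 1L
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

metric_denominator_error <- function(metric) {
  abort(paste0(metric, " undefined: zero denominator"),
        class = "strokeseg_undefined_metric")
}

#' Dice coefficient
#'
#' `2 TP / (2 TP + FP + FN)`: the harmonic mean of precision and recall.
#'
#' @param counts A [confusion()] result.
#' @return Value in \[0, 1\]; errors (rather than silently returning 0)
#'   when both masks are empty.
#' @export
dice <- function(counts) {
  with(counts, {
    if (tp + fp + fn == 0) metric_denominator_error("dice")
    2 * tp / (2 * tp + fp + fn)
  })
}

#' Precision
#'
#' `TP / (TP + FP)`.
#'
#' @inheritParams dice
#' @return Value in \[0, 1\]; errors when the prediction is empty.
#' @export
precision <- function(counts) {
  with(counts, {
    if (tp + fp == 0) metric_denominator_error("precision")
    tp / (tp + fp)
  })
}

#' Recall (sensitivity)
#'
#' `TP / (TP + FN)`.
#'
#' @inheritParams dice
#' @return Value in \[0, 1\]; errors when the truth is empty.
#' @export
recall <- function(counts) {
  with(counts, {
    if (tp + fn == 0) metric_denominator_error("recall")
    tp / (tp + fn)
  })
}

#' Boundary points of a mask in physical coordinates
#'
#' The boundary is the set of foreground voxels with at least one
#' background face-neighbour (6-neighbourhood; voxels at the grid edge
#' count as boundary). Points are voxel centres scaled by the spacing, in
#' mm.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Numeric matrix, one row per boundary point, columns x/y/z (mm).
#' @export
surface_points <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- mask$labels
  if (sum(lab) == 0L)
    abort("mask is empty: no surface", class = "strokeseg_empty_mask")
  d <- dim(lab)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  core <- function(dx, dy, dz)
    pad[(2 + dx):(d[1] + 1 + dx), (2 + dy):(d[2] + 1 + dy),
        (2 + dz):(d[3] + 1 + dz), drop = FALSE]
  nb_min <- core(1, 0, 0) & core(-1, 0, 0) & core(0, 1, 0) &
    core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  boundary <- (lab == 1L) & !nb_min
  idx <- which(boundary, arr.ind = TRUE)
  pts <- (idx - 1) %*% diag(mask$spacing)
  colnames(pts) <- c("x", "y", "z")
  pts
}

as_points <- function(x) {
  if (inherits(x, "binary_mask")) surface_points(x)
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1)
}

#' Hausdorff distance between two boundary point sets
#'
#' `max( max_e min_f D(e, f), max_f min_e D(e, f) )` with `D` the
#' Euclidean distance in mm.
#'
#' @param E,F Point matrices from [surface_points()] (or
#'   [binary_mask()]s, converted automatically).
#' @return Distance in mm.
#' @export
hausdorff <- function(E, F) {
  E <- as_points(E); F <- as_points(F)
  if (nrow(E) == 0L || nrow(F) == 0L)
    abort("point sets must be non-empty", class = "strokeseg_empty_mask")
  max(max(nearest_point_dists(E, F)), max(nearest_point_dists(F, E)))
}

#' Average symmetric surface distance
#'
#' Mean of the two directional average surface distances: each direction's
#' ASD is the mean nearest-point distance, and the two directions are
#' averaged with equal weight.
#'
#' @inheritParams hausdorff
#' @return Distance in mm.
#' @export
assd <- function(E, F) {
  E <- as_points(E); F <- as_points(F)
  if (nrow(E) == 0L || nrow(F) == 0L)
    abort("point sets must be non-empty", class = "strokeseg_empty_mask")
  (mean(nearest_point_dists(E, F)) + mean(nearest_point_dists(F, E))) / 2
}

#' Evaluate a segmentation against ground truth
#'
#' Computes the full metric report: Dice, precision, recall (voxel
#' overlap) and Hausdorff / ASSD (boundary distance, mm). Overlap metrics
#' that would divide by zero, and distances when either mask is empty, are
#' reported as `NA` rather than a silent 0; when both masks are empty no
#' metric is defined and an error is raised.
#'
#' @param pred,truth [binary_mask()]s on the same grid.
#' @return One-row tibble: `dice`, `precision`, `recall`, `hd_mm`,
#'   `assd_mm`, `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate <- function(pred, truth) {
  cts <- confusion(pred, truth)
  if (cts$tp + cts$fp + cts$fn == 0)
    abort("both masks empty: no metric is defined",
          class = "strokeseg_undefined_metric")
  safe <- function(f) tryCatch(f(cts), strokeseg_undefined_metric =
                                 function(e) NA_real_)
  both <- sum(pred$labels) > 0L && sum(truth$labels) > 0L
  hd <- assd_v <- NA_real_
  if (both) {
    pe <- surface_points(pred)
    te <- surface_points(truth)
    hd <- hausdorff(te, pe)
    assd_v <- assd(te, pe)
  }
  tibble(dice = safe(dice), precision = safe(precision),
         recall = safe(recall), hd_mm = hd, assd_mm = assd_v,
         tp = cts$tp, fp = cts$fp, fn = cts$fn, tn = cts$tn)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP ", x$tp, ", FP ", x$fp, ", FN ", x$fn,
      ", TN ", x$tn, "\n", sep = "")
  invisible(x)
}
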