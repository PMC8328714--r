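# Connected-component postprocessing of the coarse segmentation: a mean-TTP
# screen (threshold 100 gray values) followed by a relative-volume screen
# (threshold 0.1 of the largest component).
#
# Ischemic tissue peaks late, so true lesions have *elevated* mean TTP; the
# default therefore removes components whose mean TTP falls *below* the
# threshold. `ttp_removal_side = "above"` gives the opposite rule.

#' Postprocessing parameters
#'
#' @param ttp_threshold Mean-TTP screening threshold in gray values
#'   (default 100).
#' @param volume_ratio_threshold Relative-volume threshold (default 0.1):
#'   components with `v(n) / V_max` strictly below it are removed.
#' @param connectivity Voxel adjacency: 6 (faces), 18 (faces + edges) or
#'   26 (faces + edges + corners).
#' @param ttp_removal_side `"below"` (default) removes components whose
#'   mean TTP is strictly below the threshold; `"above"` removes those
#'   strictly above it.
#' @return A `postprocess_params` list.
#' @export
postprocess_params <- function(ttp_threshold = 100,
                               volume_ratio_threshold = 0.1,
                               connectivity = 26L,
                               ttp_removal_side = c("below", "above")) {
  if (!is.finite(ttp_threshold))
    abort("ttp_threshold must be finite", class = "strokeseg_value_error")
  if (volume_ratio_threshold <= 0 || volume_ratio_threshold > 1)
    abort("volume_ratio_threshold must be in (0, 1]",
          class = "strokeseg_value_error")
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("connectivity must be 6, 18 or 26", class = "strokeseg_value_error")
  structure(list(ttp_threshold = ttp_threshold,
                 volume_ratio_threshold = volume_ratio_threshold,
                 connectivity = as.integer(connectivity),
                 ttp_removal_side = match.arg(ttp_removal_side)),
            class = "postprocess_params")
}

#' Label 3-D connected components
#'
#' @param mask A [binary_mask()].
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 = background, components
#'   numbered from 1) and `n` (component count). Components are maximal
#'   under the chosen adjacency.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("connectivity must be 6, 18 or 26", class = "strokeseg_value_error")
  cc_label(mask$labels, as.integer(connectivity))
}

#' Per-component voxel counts and mean TTP
#'
#' @param components Output of [connected_components()].
#' @param ttp A [volume3d()] of TTP gray values on the same grid.
#' @return A tibble with one row per component: `component`, `voxels`,
#'   `mean_ttp` and the shared `v_max` (largest component volume).
#' @export
component_stats <- function(components, ttp) {
  stopifnot(inherits(ttp, "volume3d"))
  if (!identical(dim(components$labels), dim(ttp$data)))
    abort("component labels and TTP grids differ",
          class = "strokeseg_grid_error")
  n <- components$n
  if (n == 0L)
    return(tibble(component = integer(), voxels = integer(),
                  mean_ttp = numeric(), v_max = integer()))
  lab <- as.vector(components$labels)
  fg <- lab > 0L
  voxels <- as.integer(tabulate(lab[fg], nbins = n))
  sums <- as.vector(tapply(ttp$data[fg], lab[fg], sum))
  tibble(component = seq_len(n), voxels = voxels,
         mean_ttp = sums / voxels, v_max = max(voxels))
}

remove_components <- function(mask, components, drop_ids) {
  if (length(drop_ids) == 0L) return(mask)
  lab <- mask$labels
  lab[components$labels %in% drop_ids] <- 0L
  binary_mask(lab, spacing = mask$spacing)
}

#' Mean-TTP component screen
#'
#' Removes whole connected components whose mean TTP gray value lies
#' strictly on the removal side of the threshold; components exactly at
#' the threshold are retained.
#'
#' @param mask A [binary_mask()].
#' @param ttp A [volume3d()] on the same grid.
#' @param params A [postprocess_params()].
#' @return The screened [binary_mask()].
#' @export
ttp_filter <- function(mask, ttp, params = postprocess_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  check_same_grid(dim(mask$labels), mask$spacing, dim(ttp$data), ttp$spacing)
  comp <- connected_components(mask, params$connectivity)
  st <- component_stats(comp, ttp)
  drop <- if (params$ttp_removal_side == "below")
    st$component[st$mean_ttp < params$ttp_threshold]
  else st$component[st$mean_ttp > params$ttp_threshold]
  remove_components(mask, comp, drop)
}

#' Relative-volume component screen
#'
#' Removes components whose voxel count is strictly below
#' `volume_ratio_threshold` times the largest component's; the largest
#' component (ratio 1) always survives, as do components exactly at the
#' threshold.
#'
#' @param mask A [binary_mask()].
#' @param params A [postprocess_params()].
#' @return The screened [binary_mask()].
#' @export
volume_ratio_filter <- function(mask, params = postprocess_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  comp <- connected_components(mask, params$connectivity)
  if (comp$n == 0L) return(mask)
  voxels <- tabulate(comp$labels[comp$labels > 0L], nbins = comp$n)
  vmax <- max(voxels)
  drop <- which(voxels / vmax < params$volume_ratio_threshold)
  remove_components(mask, comp, drop)
}

#' Postprocess a coarse segmentation
#'
#' Applies the mean-TTP screen first, then the relative-volume screen.
#' Only removals happen, so the output is always a subset of the input.
#'
#' @param mask A [binary_mask()] (the coarse segmentation).
#' @param ttp A [volume3d()] of TTP gray values on the same grid.
#' @param params A [postprocess_params()].
#' @return The final [binary_mask()].
#' @export
postprocess <- function(mask, ttp, params = postprocess_params()) {
  volume_ratio_filter(ttp_filter(mask, ttp, params), params)
}
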