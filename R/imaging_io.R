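# Volume / mask data model and NIfTI I/O shared by every pipeline stage.
#
# Coordinate convention: 0-based (x, y, z) indices; every physical distance
# is index difference times voxel spacing in mm.

#' Construct a 3-D intensity volume
#'
#' A `volume3d` wraps a 3-D numeric array together with its physical voxel
#' spacing in millimetres. All intensities must be finite and all spacings
#' strictly positive.
#'
#' @param data 3-D numeric array of intensities (arbitrary units).
#' @param spacing Numeric vector of length 3, voxel size per axis in mm.
#' @return An object of class `volume3d` with elements `data` and `spacing`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(1, 1, 5))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array", class = "strokeseg_dim_error")
  if (any(dim(data) < 1L))
    abort("all volume dimensions must be >= 1", class = "strokeseg_dim_error")
  if (!all(is.finite(data)))
    abort("volume intensities must be finite", class = "strokeseg_value_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 positive values (mm)",
          class = "strokeseg_value_error")
  structure(list(data = unclass(data), spacing = spacing), class = "volume3d")
}

#' Construct a binary lesion mask
#'
#' Voxels take values in \{0, 1\}: 0 marks healthy tissue and 1 the stroke
#' lesion. The mask lives on the same grid contract as its source volume.
#'
#' @param labels 3-D array with entries 0 or 1.
#' @param spacing Voxel size per axis in mm.
#' @return An object of class `binary_mask` with elements `labels` (integer
#'   array) and `spacing`.
#' @export
binary_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    abort("`labels` must be a 3-D array", class = "strokeseg_dim_error")
  if (!all(labels %in% c(0, 1)))
    abort("mask values must be 0 or 1", class = "strokeseg_value_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    abort("`spacing` must be 3 positive values (mm)",
          class = "strokeseg_value_error")
  lab <- array(as.integer(labels), dim = dim(labels))
  structure(list(labels = lab, spacing = spacing), class = "binary_mask")
}

#' Construct a per-voxel class probability map
#'
#' Stores one probability per class and voxel as a 4-D array whose **last**
#' dimension indexes the class (background first, lesion second for the
#' two-class case). Probabilities must lie in \[0, 1\] and sum to 1 over
#' classes at every voxel (tolerance 1e-6).
#'
#' @param probs 4-D numeric array, dim `(nx, ny, nz, k)` with `k >= 2`.
#' @param spacing Voxel size per axis in mm.
#' @return An object of class `prob_map`.
#' @export
probability_map <- function(probs, spacing = c(1, 1, 1)) {
  if (!is.array(probs) || length(dim(probs)) != 4L)
    abort("`probs` must be a 4-D array (x, y, z, class)",
          class = "strokeseg_dim_error")
  k <- dim(probs)[4]
  if (k < 2L)
    abort("at least 2 classes required", class = "strokeseg_value_error")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    abort("probabilities must lie in [0, 1]", class = "strokeseg_value_error")
  sums <- rowSums(matrix(probs, ncol = k))
  if (any(abs(sums - 1) > 1e-6))
    abort("per-voxel class probabilities must sum to 1 (tol 1e-6)",
          class = "strokeseg_value_error")
  spacing <- as.numeric(spacing)
  structure(list(probs = unclass(probs), spacing = spacing),
            class = "prob_map")
}

#' Bundle co-registered modality volumes into one stack
#'
#' @param volumes Named list of [volume3d()] objects on one common grid
#'   (identical dimensions and spacing), e.g. T1/T2/FLAIR/DWI/TTP.
#' @return An object of class `modality_stack`: the validated named list,
#'   channel order preserved.
#' @export
stack_modalities <- function(volumes) {
  if (!is.list(volumes) || length(volumes) < 1L)
    abort("need at least one volume", class = "strokeseg_value_error")
  nm <- names(volumes)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    abort("volumes must have unique non-empty names",
          class = "strokeseg_value_error")
  for (v in volumes)
    if (!inherits(v, "volume3d"))
      abort("all elements must be volume3d objects",
            class = "strokeseg_value_error")
  ref <- volumes[[1]]
  for (v in volumes[-1]) {
    if (!identical(dim(v$data), dim(ref$data)))
      abort("channel dimensions differ", class = "strokeseg_grid_error")
    if (max(abs(v$spacing - ref$spacing)) > 1e-9)
      abort("channel spacings differ", class = "strokeseg_grid_error")
  }
  structure(volumes, class = "modality_stack")
}

#' Read a 3-D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D image.
#' @return A [volume3d()] whose dimensions and spacing match the file header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "strokeseg_io_error")
  img <- RNifti::readNifti(path)
  if (RNifti::ndim(img) != 3L)
    abort("expected a 3-D NIfTI image", class = "strokeseg_dim_error")
  volume3d(array(as.numeric(img), dim = dim(img)),
           spacing = RNifti::pixdim(img)[1:3])
}

# Written through oro.nifti, which keeps singleton trailing dimensions
# (single-slice volumes stay 3-D on disk).
write_nifti_3d <- function(data, spacing, path, datatype, bitpix) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    abort("path must end in .nii or .nii.gz", class = "strokeseg_io_error")
  base <- sub("\\.nii(\\.gz)?$", "", path)
  gz <- grepl("\\.gz$", path)
  img <- oro.nifti::nifti(data, datatype = datatype, bitpix = bitpix,
                          pixdim = c(1, spacing, rep(0, 4)))
  tryCatch(suppressWarnings(oro.nifti::writeNIfTI(img, base, gzipped = gz)),
           error = function(e) abort(conditionMessage(e),
                                     class = "strokeseg_io_error"))
  invisible(path)
}

#' Write a 3-D volume to a NIfTI file
#'
#' Stored as double precision so intensities round-trip losslessly.
#'
#' @param volume A [volume3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  write_nifti_3d(volume$data, volume$spacing, path,
                 datatype = 64L, bitpix = 64L)
}

#' Read a binary mask from a NIfTI file
#'
#' @param path Path to a NIfTI file containing values in \{0, 1\}.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data, v$spacing)
}

#' Write a binary mask to a NIfTI file
#'
#' Masks are stored as unsigned 8-bit integers.
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_nifti_3d(mask$labels, mask$spacing, path,
                 datatype = 2L, bitpix = 8L)
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", sum(x$labels), " foreground\n", sep = "")
  invisible(x)
}

#' @export
print.modality_stack <- function(x, ...) {
  cat("<modality_stack> channels: ", paste(names(x), collapse = ", "),
      "; grid ", paste(dim(x[[1]]$data), collapse = " x "), "\n", sep = "")
  invisible(x)
}

# internal: shared grid checks
check_same_grid <- function(dim_a, sp_a, dim_b, sp_b) {
  if (!identical(as.integer(dim_a), as.integer(dim_b)))
    abort("grids differ in dimensions", class = "strokeseg_grid_error")
  if (max(abs(sp_a - sp_b)) > 1e-9)
    abort("grids differ in spacing", class = "strokeseg_grid_error")
  invisible(TRUE)
}
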