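# Synthetic multimodal MRI lesion phantoms with known ground truth.
#
# Each phantom carries the five acquisition channels of a typical stroke
# protocol (T1, T2, FLAIR, DWI) plus a TTP perfusion map. Lesions are
# axis-aligned ellipsoids whose mean intensity differs from background per
# channel; ischemic tissue has *elevated* TTP. Noise is i.i.d. Gaussian.

default_channel_model <- function() {
  list(
    T1    = c(background_mean = 100, lesion_mean = 70,  noise_sd = 5),
    T2    = c(background_mean = 80,  lesion_mean = 120, noise_sd = 5),
    FLAIR = c(background_mean = 70,  lesion_mean = 130, noise_sd = 5),
    DWI   = c(background_mean = 60,  lesion_mean = 140, noise_sd = 5)
  )
}

#' Configuration of the synthetic lesion phantom generator
#'
#' @param shape Integer grid dimensions `(nx, ny, nz)`; single-slice
#'   phantoms use `nz = 1`.
#' @param spacing Voxel size per axis in mm.
#' @param n_lesions Number of ellipsoidal lesions (>= 0); overlapping
#'   lesions merge by union.
#' @param radius_range `(min, max)` ellipsoid semi-axis in voxels; each
#'   semi-axis is drawn uniformly from this range. Axes of size 1 (e.g. a
#'   single slice) get a degenerate semi-axis of 0.5.
#' @param channel_model Named list; per channel a numeric vector
#'   `(background_mean, lesion_mean, noise_sd)` in intensity units.
#' @param ttp_model The same triple for the TTP perfusion channel
#'   (gray-value units). Default background 60, lesion 120: ischemic tissue
#'   peaks late, so its mean TTP sits well above the postprocessing
#'   threshold of 100 while healthy tissue sits below it.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 1),
                           spacing = c(1, 1, 5),
                           n_lesions = 1,
                           radius_range = c(5, 12),
                           channel_model = default_channel_model(),
                           ttp_model = c(background_mean = 60,
                                         lesion_mean = 120,
                                         noise_sd = 8),
                           seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  radius_range <- as.numeric(radius_range)
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2] ||
      radius_range[1] <= 0)
    abort("radius_range must be (min, max) with 0 < min <= max",
          class = "strokeseg_value_error")
  if (n_lesions < 0)
    abort("n_lesions must be >= 0", class = "strokeseg_value_error")
  for (cm in c(channel_model, list(ttp_model))) {
    if (length(cm) != 3L || any(!is.finite(cm)) || cm[3] < 0)
      abort("channel models are (background_mean, lesion_mean, noise_sd), noise_sd >= 0",
            class = "strokeseg_value_error")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 radius_range = radius_range,
                 channel_model = channel_model,
                 ttp_model = ttp_model, seed = as.integer(seed)),
            class = "phantom_config")
}

# Place n ellipsoids fully inside the grid; returns logical truth array.
# Axes with a single voxel get a fixed 0.5 semi-axis.
place_lesions <- function(shape, n_lesions, radius_range, max_tries = 100L) {
  truth <- array(FALSE, dim = shape)
  if (n_lesions == 0L) return(truth)
  coords <- lapply(seq_len(3L), function(a) seq_len(shape[a]))
  for (l in seq_len(n_lesions)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- numeric(3)
      ctr <- numeric(3)
      ok <- TRUE
      for (a in 1:3) {
        if (shape[a] == 1L) {
          r[a] <- 0.5
          ctr[a] <- 1
        } else {
          r[a] <- runif(1, radius_range[1], radius_range[2])
          lo <- ceiling(1 + r[a])
          hi <- floor(shape[a] - r[a])
          if (lo > hi) { ok <- FALSE; break }
          ctr[a] <- sample(lo:hi, 1L)
        }
      }
      if (!ok) next
      dx2 <- ((coords[[1]] - ctr[1]) / r[1])^2
      dy2 <- ((coords[[2]] - ctr[2]) / r[2])^2
      dz2 <- ((coords[[3]] - ctr[3]) / r[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
      if (!any(inside)) next
      truth <- truth | inside
      placed <- TRUE
      break
    }
    if (!placed)
      abort("could not place lesion inside grid: radius too large",
            class = "strokeseg_placement_error")
  }
  truth
}

#' Generate one synthetic multimodal phantom
#'
#' Voxel intensity is tissue mean plus i.i.d. Gaussian noise per the
#' channel model; the ground-truth mask marks exactly the ellipsoid union.
#' Generation is deterministic given `config$seed` and leaves the caller's
#' RNG state untouched.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_sample`: list with `stack` (a [stack_modalities()]
#'   including a `"TTP"` channel) and `truth` (a [binary_mask()]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  shape <- config$shape
  truth <- place_lesions(shape, config$n_lesions, config$radius_range)
  models <- c(config$channel_model, list(TTP = config$ttp_model))
  vols <- lapply(models, function(cm) {
    v <- array(cm[[1]], dim = shape)
    v[truth] <- cm[[2]]
    if (cm[[3]] > 0) v <- v + array(rnorm(prod(shape), sd = cm[[3]]), dim = shape)
    volume3d(v, spacing = config$spacing)
  })
  structure(list(stack = stack_modalities(vols),
                 truth = binary_mask(array(as.integer(truth), dim = shape),
                                     spacing = config$spacing),
                 config = config),
            class = "phantom_sample")
}

#' Generate a reproducible phantom dataset
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' the whole dataset is bit-reproducible while samples differ from each
#' other.
#'
#' @param config A [phantom_config()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param n Number of samples (>= 1).
#' @param seed Master seed.
#' @return List of `n` phantom samples.
#' @export
generate_dataset <- function(config, n, seed = config$seed) {
  if (!is.numeric(n) || n < 1)
    abort("n must be >= 1", class = "strokeseg_value_error")
  n <- as.integer(n)
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    generate_phantom(cfg)
  })
}

# Deterministic per-stage / per-sample seed derivation (< 2^31).
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample> grid ", paste(dim(x$truth$labels), collapse = " x "),
      ", lesion voxels ", sum(x$truth$labels), ", channels: ",
      paste(names(x$stack), collapse = ", "), "\n", sep = "")
  invisible(x)
}
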