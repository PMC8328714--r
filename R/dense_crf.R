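# Fully connected CRF over the voxel grid with Potts compatibility and a
# two-kernel Gaussian pairwise potential (appearance + smoothness),
# refined by exact mean-field inference. Pairwise sums are computed
# densely -- no lattice approximation -- which is feasible at desk scale
# and lets small instances be checked against exhaustive enumeration.
#
# Energy convention: E(y) = sum_i u_i(y_i) + sum_{i<j} w_ij(y_i, y_j) and
# p(y) = exp(-E(y)) / Z, so low-energy labelings are likely.

#' CRF parameters
#'
#' @param w1 Weight of the appearance kernel (position + intensity).
#' @param w2 Weight of the smoothness kernel (position only).
#' @param sigma_alpha Position bandwidth of the appearance kernel (voxels).
#' @param sigma_beta Intensity bandwidth of the appearance kernel
#'   (intensity units).
#' @param sigma_gamma Position bandwidth of the smoothness kernel (voxels).
#' @param iterations Mean-field iterations (>= 1).
#' @return A `crf_params` list. Compatibility is Potts: a pairwise penalty
#'   applies only when two voxels take different labels.
#' @export
crf_params <- function(w1 = 1, w2 = 1, sigma_alpha = 3, sigma_beta = 10,
                       sigma_gamma = 3, iterations = 5L) {
  if (any(c(sigma_alpha, sigma_beta, sigma_gamma) <= 0))
    abort("bandwidths must be > 0", class = "strokeseg_value_error")
  if (w1 < 0 || w2 < 0)
    abort("kernel weights must be >= 0", class = "strokeseg_value_error")
  if (iterations < 1)
    abort("iterations must be >= 1", class = "strokeseg_value_error")
  structure(list(w1 = w1, w2 = w2, sigma_alpha = sigma_alpha,
                 sigma_beta = sigma_beta, sigma_gamma = sigma_gamma,
                 iterations = as.integer(iterations)),
            class = "crf_params")
}

#' Unary energies from a probability map
#'
#' The unary potential is the negative log of the network's per-voxel class
#' probability, clamped at `eps` so it stays finite.
#'
#' @param probs A [probability_map()], or a numeric matrix `N x k`.
#' @param eps Clamping floor.
#' @return Matrix `N x k` of unary energies (voxels in column-major grid
#'   order).
#' @export
unary_from_probs <- function(probs, eps = 1e-12) {
  p <- if (inherits(probs, "prob_map")) {
    k <- dim(probs$probs)[4]
    matrix(probs$probs, ncol = k)
  } else as.matrix(probs)
  -log(pmax(p, eps))
}

#' Pairwise (binary) potential between two voxels
#'
#' Potts-modulated two-kernel Gaussian potential: zero for equal labels;
#' for differing labels,
#' `w1 * exp(-|p_i-p_j|^2 / (2 sigma_alpha^2) - |I_i-I_j|^2 / (2 sigma_beta^2))
#'  + w2 * exp(-|p_i-p_j|^2 / (2 sigma_gamma^2))`.
#'
#' @param label_i,label_j Class labels.
#' @param p_i,p_j Numeric position vectors (voxel coordinates).
#' @param I_i,I_j Scalar intensities.
#' @param params A [crf_params()].
#' @return Non-negative energy.
#' @export
pairwise_energy <- function(label_i, label_j, p_i, p_j, I_i, I_j, params) {
  stopifnot(inherits(params, "crf_params"))
  if (identical(label_i, label_j)) return(0)
  d2 <- sum((p_i - p_j)^2)
  di2 <- (I_i - I_j)^2
  params$w1 * exp(-d2 / (2 * params$sigma_alpha^2) -
                    di2 / (2 * params$sigma_beta^2)) +
    params$w2 * exp(-d2 / (2 * params$sigma_gamma^2))
}

# voxel-centre coordinates (in voxels) and intensity vector of a volume,
# flattened in column-major grid order
grid_features <- function(image) {
  d <- dim(image$data)
  pos <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                               y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  list(pos = pos, intens = as.vector(image$data))
}

build_kernel <- function(image, params) {
  gf <- grid_features(image)
  crf_kernel_matrix(gf$pos, gf$intens, params$w1, params$w2,
                    params$sigma_alpha, params$sigma_beta,
                    params$sigma_gamma)
}

#' Total Gibbs energy of a labeling
#'
#' Sum of unary energies at the assigned labels plus the pairwise potential
#' over all unordered voxel pairs.
#'
#' @param labeling Integer vector (or array) of class indices in `1..k`,
#'   one per voxel, column-major grid order.
#' @param unary Matrix `N x k` of unary energies (see
#'   [unary_from_probs()]).
#' @param image A [volume3d()] supplying positions and intensities.
#' @param params A [crf_params()].
#' @return Scalar energy.
#' @export
total_energy <- function(labeling, unary, image, params) {
  y <- as.integer(labeling)
  n <- nrow(unary)
  if (length(y) != n || n != length(image$data))
    abort("labeling, unary and image sizes differ",
          class = "strokeseg_grid_error")
  K <- build_kernel(image, params)
  diff <- outer(y, y, `!=`)
  sum(unary[cbind(seq_len(n), y)]) + sum(K[diff]) / 2
}

enumerate_labelings <- function(n, k = 2L) {
  if (k^n > 70000)
    abort("instance too large to enumerate", class = "strokeseg_capacity_error")
  as.matrix(expand.grid(rep(list(seq_len(k)), n)))
}

#' Exhaustive Gibbs distribution over all labelings
#'
#' Enumerates every labeling of a small instance (capacity-limited) and
#' returns energies and normalized Gibbs probabilities. This is the exact
#' reference against which mean-field inference is validated.
#'
#' @inheritParams total_energy
#' @param k Number of classes.
#' @return List with `labelings` (matrix, one row per labeling),
#'   `energy` and `prob` vectors; `prob` sums to 1 by construction of the
#'   partition value.
#' @export
gibbs_partition <- function(unary, image, params, k = ncol(unary)) {
  n <- nrow(unary)
  labs <- enumerate_labelings(n, k)
  K <- build_kernel(image, params)
  energy <- apply(labs, 1, function(y) {
    diff <- outer(y, y, `!=`)
    sum(unary[cbind(seq_len(n), y)]) + sum(K[diff]) / 2
  })
  w <- exp(-(energy - min(energy)))
  list(labelings = labs, energy = energy, prob = w / sum(w))
}

#' Gibbs probability of one labeling
#'
#' `exp(-E(y)) / Z` with the partition value `Z` summed over the full
#' labeling space (so the instance must be small enough to enumerate,
#' roughly <= 16 voxels for two classes).
#'
#' @inheritParams total_energy
#' @param k Number of classes.
#' @return Probability in (0, 1].
#' @export
gibbs_probability <- function(labeling, unary, image, params,
                              k = ncol(unary)) {
  gp <- gibbs_partition(unary, image, params, k)
  y <- as.integer(labeling)
  hit <- which(apply(gp$labelings, 1, function(r) all(r == y)))
  gp$prob[hit]
}

#' Mean-field refinement of a probability map
#'
#' Iterates the fully factorized mean-field update
#' `Q_i(c) \propto exp(-u_i(c) - sum_{j != i} k_ij (1 - Q_j(c)))`
#' (the Potts form of the generic update), normalizing marginals each
#' iteration. With both kernel weights zero there is no coupling and the
#' input distribution is already the fixed point, so refinement returns it
#' unchanged.
#'
#' @param probs A [probability_map()] from the network.
#' @param image A [volume3d()] on the same grid: the reference intensity
#'   field entering the appearance kernel (by default the first channel of
#'   the modality stack in the pipeline).
#' @param params A [crf_params()].
#' @return A `crf_result`: list with `probs` (refined
#'   [probability_map()]) and `map` (the maximum a-posteriori
#'   [binary_mask()], ties to background).
#' @export
mean_field_refine <- function(probs, image, params = crf_params()) {
  stopifnot(inherits(probs, "prob_map"), inherits(image, "volume3d"))
  d <- dim(probs$probs)
  check_same_grid(d[1:3], probs$spacing, dim(image$data), image$spacing)
  k <- d[4]
  Q <- matrix(probs$probs, ncol = k)
  if (params$w1 + params$w2 > 0) {
    u <- unary_from_probs(probs)
    K <- build_kernel(image, params)
    s <- rowSums(K)
    for (it in seq_len(params$iterations)) {
      msg <- s - K %*% Q              # N x k: sum_j k_ij (1 - Q_j(c))
      logq <- -u - msg
      logq <- logq - do.call(pmax, lapply(seq_len(k), function(j) logq[, j]))
      Q <- exp(logq)
      Q <- Q / rowSums(Q)
    }
  }
  out <- probability_map(array(Q, dim = d), spacing = probs$spacing)
  # ties go to background: "first" prefers the background column
  map_lab <- max.col(Q, ties.method = "first")
  map <- binary_mask(array(as.integer(map_lab == 2L), dim = d[1:3]),
                     spacing = probs$spacing)
  structure(list(probs = out, map = map, params = params),
            class = "crf_result")
}

#' @export
print.crf_result <- function(x, ...) {
  cat("<crf_result> grid ", paste(dim(x$map$labels), collapse = " x "),
      ", MAP foreground ", sum(x$map$labels), " voxels\n", sep = "")
  invisible(x)
}
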