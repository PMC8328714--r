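# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own computational paths: confusion counts are taken
# by explicit voxel comparison, distances by full all-pairs matrices.

random_blob_mask <- function(dims, seed, p = 0.15, spacing = c(1, 1, 1)) {
  set.seed(seed)
  lab <- array(as.integer(runif(prod(dims)) < p), dim = dims)
  if (sum(lab) == 0L) lab[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                          ceiling(dims[3] / 2)] <- 1L
  binary_mask(lab, spacing = spacing)
}

oracle_counts <- function(pred, truth) {
  p <- as.vector(pred$labels)
  t <- as.vector(truth$labels)
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(p)) {
    if (p[i] == 1L && t[i] == 1L) tp <- tp + 1L
    else if (p[i] == 1L) fp <- fp + 1L
    else if (t[i] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# boundary points recomputed independently: walk the foreground voxels and
# check the six face neighbours explicitly
oracle_surface_points <- function(mask) {
  lab <- mask$labels
  d <- dim(lab)
  fg <- which(lab == 1L, arr.ind = TRUE)
  keep <- logical(nrow(fg))
  for (r in seq_len(nrow(fg))) {
    i <- fg[r, 1]; j <- fg[r, 2]; k <- fg[r, 3]
    nb <- c(
      if (i > 1) lab[i - 1, j, k] else 0L,
      if (i < d[1]) lab[i + 1, j, k] else 0L,
      if (j > 1) lab[i, j - 1, k] else 0L,
      if (j < d[2]) lab[i, j + 1, k] else 0L,
      if (k > 1) lab[i, j, k - 1] else 0L,
      if (k < d[3]) lab[i, j, k + 1] else 0L)
    keep[r] <- any(nb == 0L)
  }
  pts <- (fg[keep, , drop = FALSE] - 1) %*% diag(mask$spacing)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# full all-pairs distance matrix, per-coordinate differences
oracle_dist_matrix <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2 +
    outer(A[, 3], B[, 3], `-`)^2
  sqrt(d2)
}

oracle_hd <- function(A, B) {
  D <- oracle_dist_matrix(A, B)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

oracle_assd <- function(A, B) {
  D <- oracle_dist_matrix(A, B)
  (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
}

# independent energy evaluation for tiny CRF instances: nested loops over
# unordered pairs, kernel written out from the potential's definition
oracle_total_energy <- function(y, unary, image, params) {
  d <- dim(image$data)
  pos <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1,
                               seq_len(d[3]) - 1))
  intens <- as.vector(image$data)
  n <- length(y)
  e <- 0
  for (i in seq_len(n)) e <- e + unary[i, y[i]]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (y[i] == y[j]) next
    d2 <- sum((pos[i, ] - pos[j, ])^2)
    di2 <- (intens[i] - intens[j])^2
    e <- e + params$w1 * exp(-d2 / (2 * params$sigma_alpha^2) -
                               di2 / (2 * params$sigma_beta^2)) +
      params$w2 * exp(-d2 / (2 * params$sigma_gamma^2))
  }
  e
}

# a seeded random small attractive-Potts instance (<= 12 voxels)
random_crf_instance <- function(seed) {
  set.seed(seed)
  repeat {
    d <- sample(1:3, 3, replace = TRUE)
    if (prod(d) >= 2 && prod(d) <= 12) break
  }
  n <- prod(d)
  img <- volume3d(array(runif(n, 0, 50), dim = d))
  p_les <- runif(n, 0.05, 0.95)
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(d, 2)))
  params <- crf_params(w1 = runif(1, 0.1, 1.5), w2 = runif(1, 0.1, 1.5),
                       sigma_alpha = runif(1, 1, 4),
                       sigma_beta = runif(1, 5, 30),
                       sigma_gamma = runif(1, 1, 4), iterations = 20)
  list(probs = probs, img = img, params = params, dims = d)
}

tiny_pipeline_config <- function(seed = 3) {
  validate_config(list(
    seed = seed,
    phantom = list(shape = c(16, 16, 1), radius_range = c(3, 5),
                   n_train = 6, n_eval = 2),
    network = list(depth = 2, base_channels = 4),
    train = list(max_iterations = 40, batch_size = 4),
    crf = list(iterations = 2)))
}
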