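test_that("unary energies are the clamped negative log probabilities", {
  p <- probability_map(array(c(1, 0.5, 0, 0.5), dim = c(2, 1, 1, 2)))
  u <- unary_from_probs(p)
  expect_equal(u[1, 1], 0)           # p = 1
  expect_equal(u[2, 1], log(2))      # p = 0.5
  expect_true(is.finite(u[1, 2]))    # p = 0 clamped, not infinite
  # uniform map: equal unaries across classes
  pu <- probability_map(array(0.5, dim = c(2, 2, 1, 2)))
  uu <- unary_from_probs(pu)
  expect_true(all(uu[, 1] == uu[, 2]))
})

test_that("pairwise potential matches its closed forms", {
  pr <- crf_params(w1 = 0.7, w2 = 0.4, sigma_alpha = 2, sigma_beta = 10,
                   sigma_gamma = 3)
  # Potts: equal labels cost nothing
  expect_equal(pairwise_energy(1, 1, c(0, 0, 0), c(5, 0, 0), 10, 90, pr), 0)
  # zero-distance limit: both exponentials are 1
  expect_equal(pairwise_energy(1, 2, c(1, 2, 3), c(1, 2, 3), 50, 50, pr),
               0.7 + 0.4)
  # |p_i - p_j| = sigma_alpha, equal intensity, w2 = 0
  pr2 <- crf_params(w1 = 1.3, w2 = 0, sigma_alpha = 2, sigma_beta = 10,
                    sigma_gamma = 3)
  expect_equal(pairwise_energy(1, 2, c(0, 0, 0), c(2, 0, 0), 80, 80, pr2),
               1.3 * exp(-0.5))
})

test_that("total energy agrees with an independent pairwise-loop oracle", {
  set.seed(10)
  img <- volume3d(array(runif(4, 0, 100), dim = c(2, 2, 1)))
  p_les <- runif(4, 0.1, 0.9)
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(2, 2, 1, 2)))
  u <- unary_from_probs(probs)
  pr <- crf_params(w1 = 0.9, w2 = 0.6, sigma_alpha = 1.5, sigma_beta = 20,
                   sigma_gamma = 2.5)
  labs <- as.matrix(expand.grid(rep(list(1:2), 4)))
  for (r in seq_len(nrow(labs))) {
    y <- labs[r, ]
    expect_equal(total_energy(y, u, img, pr),
                 oracle_total_energy(y, u, img, pr))
  }
  # single voxel with p(lesion) = 1 labeled lesion: zero energy
  img1 <- volume3d(array(5, dim = c(1, 1, 1)))
  u1 <- unary_from_probs(matrix(c(0, 1), 1))
  expect_equal(total_energy(2L, u1, img1, pr), 0)
  # same labels everywhere: pairwise vanishes, unary sum remains
  e_same <- total_energy(rep(1L, 4), u, img, pr)
  expect_equal(e_same, sum(u[, 1]))
})

test_that("Gibbs distribution normalizes and factorizes without coupling", {
  set.seed(11)
  img <- volume3d(array(runif(4, 0, 10), dim = c(2, 2, 1)))
  p_les <- runif(4, 0.2, 0.8)
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(2, 2, 1, 2)))
  u <- unary_from_probs(probs)
  pr <- crf_params(w1 = 1, w2 = 1)
  gp <- gibbs_partition(u, img, pr)
  expect_equal(sum(gp$prob), 1, tolerance = 1e-12)
  expect_equal(nrow(gp$labelings), 16)

  # no pairwise coupling: joint factorizes into per-voxel softmax of -u
  pr0 <- crf_params(w1 = 0, w2 = 0)
  gp0 <- gibbs_partition(u, img, pr0)
  site <- exp(-u) / rowSums(exp(-u))
  for (r in seq_len(nrow(gp0$labelings))) {
    y <- gp0$labelings[r, ]
    expect_equal(gp0$prob[r],
                 prod(site[cbind(1:4, y)]), tolerance = 1e-9)
  }
  # uniform unaries, no coupling: uniform over labelings
  uu <- matrix(log(2), 4, 2)
  gpu <- gibbs_partition(uu, img, pr0)
  expect_equal(gpu$prob, rep(1 / 16, 16))
  # gibbs_probability picks the right labeling
  expect_equal(gibbs_probability(c(1, 1, 1, 1), u, img, pr),
               gp$prob[which(apply(gp$labelings, 1,
                                   function(r) all(r == 1)))])
  # capacity guard
  big_u <- matrix(0.5, 20, 2)
  big_img <- volume3d(array(0, dim = c(20, 1, 1)))
  expect_error(gibbs_partition(big_u, big_img, pr),
               class = "strokeseg_capacity_error")
})

test_that("zero kernel weights make refinement the exact identity", {
  set.seed(12)
  d <- c(4, 4, 2)
  p_les <- runif(prod(d), 0.01, 0.99)
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(d, 2)))
  img <- volume3d(array(runif(prod(d)), dim = d))
  for (iters in c(1, 7)) {
    res <- mean_field_refine(probs, img,
                             crf_params(w1 = 0, w2 = 0, iterations = iters))
    expect_identical(res$probs$probs, probs$probs)
  }
})

test_that("attractive coupling flips an isolated low-confidence voxel", {
  d <- c(3, 3, 1)
  p_les <- rep(0.9, 9)
  p_les[5] <- 0.4                        # center disagrees with its ring
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(d, 2)))
  img <- volume3d(array(50, dim = d))    # uniform intensity
  pr <- crf_params(w1 = 1, w2 = 1, sigma_alpha = 3, sigma_beta = 10,
                   sigma_gamma = 3, iterations = 10)
  res <- mean_field_refine(probs, img, pr)
  expect_identical(res$map$labels[2, 2, 1], 1L)
  # and this matches the exhaustive minimum-energy labeling
  gp <- gibbs_partition(unary_from_probs(probs), img, pr)
  exact <- gp$labelings[which.min(gp$energy), ]
  expect_identical(as.integer(as.vector(res$map$labels)) + 1L,
                   as.integer(exact))
})

test_that("marginals stay normalized at every iteration count", {
  set.seed(13)
  d <- c(4, 3, 1)
  p_les <- runif(prod(d), 0.05, 0.95)
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(d, 2)))
  img <- volume3d(array(runif(prod(d), 0, 30), dim = d))
  for (iters in 1:4) {
    res <- mean_field_refine(probs, img, crf_params(iterations = iters))
    sums <- rowSums(matrix(res$probs$probs, ncol = 2))
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("refinement commutes with class relabeling", {
  set.seed(14)
  d <- c(3, 3, 1)
  p_les <- runif(prod(d), 0.1, 0.9)
  probs <- probability_map(array(c(1 - p_les, p_les), dim = c(d, 2)))
  swapped <- probability_map(array(c(p_les, 1 - p_les), dim = c(d, 2)))
  img <- volume3d(array(runif(prod(d), 0, 20), dim = d))
  pr <- crf_params(iterations = 5)
  a <- mean_field_refine(probs, img, pr)
  b <- mean_field_refine(swapped, img, pr)
  expect_equal(a$probs$probs[, , , 2], b$probs$probs[, , , 1])
  expect_equal(a$probs$probs[, , , 1], b$probs$probs[, , , 2])
})

test_that("parameter validation rejects degenerate values", {
  expect_error(crf_params(sigma_alpha = 0), class = "strokeseg_value_error")
  expect_error(crf_params(w1 = -1), class = "strokeseg_value_error")
  expect_error(crf_params(iterations = 0), class = "strokeseg_value_error")
})
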