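make_stack <- function(h, w, channels, seed = 1, nz = 1) {
  set.seed(seed)
  vols <- lapply(channels, function(ch)
    volume3d(array(rnorm(h * w * nz), dim = c(h, w, nz))))
  stack_modalities(setNames(vols, channels))
}

test_that("freshly built models have every bias at zero", {
  m <- build_model(list(in_channels = 4, depth = 2, base_channels = 8))
  for (p in m$params) expect_true(all(p$b == 0))
})

test_that("forward output sits on the input grid and normalizes", {
  m <- build_model(list(in_channels = 2, depth = 1, base_channels = 4))
  s <- make_stack(32, 32, c("A", "B"))
  out <- net_forward(m, s)
  expect_equal(dim(out$main$probs), c(32, 32, 1, 2))
  expect_equal(dim(out$aux$probs), c(32, 32, 1, 2))
  sums <- rowSums(matrix(out$main$probs, ncol = 2))
  expect_true(all(abs(sums - 1) < 1e-6))
  # purity: repeated forwards agree bit-for-bit
  out2 <- net_forward(m, s)
  expect_identical(out$main$probs, out2$main$probs)
})

test_that("odd input sizes pass through the crop layer correctly", {
  m <- build_model(list(in_channels = 1, depth = 2, base_channels = 2))
  s <- make_stack(21, 27, "A", seed = 3)
  out <- net_forward(m, s)
  expect_equal(dim(out$main$probs), c(21, 27, 1, 2))
  expect_true(all(abs(rowSums(matrix(out$main$probs, ncol = 2)) - 1) < 1e-6))
})

test_that("zero weights give the uniform map and an all-background mask", {
  m <- build_model(list(in_channels = 2, depth = 1, base_channels = 4))
  m$params <- lapply(m$params, function(p) {
    p$w[] <- 0
    p
  })
  s <- make_stack(16, 16, c("A", "B"))
  out <- net_forward(m, s)
  expect_true(all(out$main$probs == 0.5))
  pr <- predict(m, s)
  expect_identical(sum(pr$mask$labels), 0L)  # ties go to background
})

test_that("spatial collapse under too much pooling is a config error", {
  expect_error(build_model(list(in_channels = 1, depth = 5,
                                base_channels = 2, input_size = c(16, 16))),
               class = "strokeseg_config_error")
  m <- build_model(list(in_channels = 1, depth = 5, base_channels = 2))
  s <- make_stack(16, 16, "A")
  expect_error(net_forward(m, s), class = "strokeseg_config_error")
})

test_that("channel mismatch is rejected", {
  m <- build_model(list(in_channels = 3, depth = 1, base_channels = 2))
  s <- make_stack(16, 16, c("A", "B"))
  expect_error(net_forward(m, s), class = "strokeseg_config_error")
})

test_that("analytic gradients match finite differences", {
  lw <- c(0.8, 0.2)
  loss_at <- function(params, arch, x, y) {
    f <- strokeseg:::unet_forward_array(params, arch, x)
    combined_loss(strokeseg:::ce_loss_array(f$main, y),
                  strokeseg:::ce_loss_array(f$aux, y), lw)
  }
  check_model <- function(depth, h, w, cin, seed) {
    m <- build_model(list(in_channels = cin, depth = depth,
                          base_channels = 2, seed = seed))
    set.seed(seed)
    x <- array(rnorm(h * w * cin * 2), dim = c(h, w, cin, 2))
    y <- array(rbinom(h * w * 2, 1, 0.5), dim = c(h, w, 2))
    fwd <- strokeseg:::unet_forward_array(m$params, m$arch, x,
                                          keep_cache = TRUE)
    grads <- strokeseg:::unet_backward_array(m$params, m$arch, fwd, y, lw)
    eps <- 1e-6
    for (nm in names(m$params)) for (slot in c("w", "b")) {
      arr <- m$params[[nm]][[slot]]
      for (i in sample(length(arr), min(3, length(arr)))) {
        p <- m$params
        p[[nm]][[slot]][i] <- arr[i] + eps
        up <- loss_at(p, m$arch, x, y)
        p[[nm]][[slot]][i] <- arr[i] - eps
        dn <- loss_at(p, m$arch, x, y)
        num <- (up - dn) / (2 * eps)
        ana <- grads[[nm]][[slot]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-2)
      }
    }
  }
  check_model(depth = 1, h = 8, w = 10, cin = 2, seed = 11)
  check_model(depth = 2, h = 13, w = 11, cin = 3, seed = 12)  # odd dims
})

test_that("training with zero learning rate leaves parameters unchanged", {
  cfg <- phantom_config(shape = c(16, 16, 1), radius_range = c(3, 5))
  ds <- generate_dataset(cfg, 2, seed = 3)
  m <- build_model(list(channels = names(ds[[1]]$stack), depth = 1,
                        base_channels = 2))
  m2 <- train_network(m, ds, train_config(learning_rate = 0,
                                          max_iterations = 1,
                                          batch_size = 2))
  expect_identical(m2$params, m$params)
})

test_that("training reduces the loss on noise-free phantoms", {
  cm <- lapply(strokeseg:::default_channel_model(), function(x) {
    x["noise_sd"] <- 0
    x
  })
  cfg <- phantom_config(shape = c(32, 32, 1), radius_range = c(4, 9),
                        channel_model = cm,
                        ttp_model = c(60, 120, 0))
  ds <- generate_dataset(cfg, 20, seed = 21)
  m <- build_model(list(channels = c("T1", "T2", "FLAIR", "DWI"),
                        depth = 2, base_channels = 4, seed = 2))
  m <- train_network(m, ds, train_config(max_iterations = 200,
                                         batch_size = 4, seed = 5))
  expect_lt(m$history$combined_loss[200], m$history$combined_loss[1])
  expect_equal(m$iterations_trained, 200L)
})

test_that("training is reproducible run-to-run with a fixed seed", {
  cfg <- phantom_config(shape = c(16, 16, 1), radius_range = c(3, 5))
  ds <- generate_dataset(cfg, 3, seed = 8)
  m0 <- build_model(list(channels = names(ds[[1]]$stack), depth = 1,
                         base_channels = 2, seed = 4))
  tc <- train_config(max_iterations = 10, batch_size = 2, seed = 6)
  m1 <- train_network(m0, ds, tc)
  m2 <- train_network(m0, ds, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history$combined_loss, m2$history$combined_loss)
})

test_that("empty datasets and default configuration behave as specified", {
  m <- build_model(list(in_channels = 1, depth = 1, base_channels = 2))
  expect_error(train_network(m, list(), train_config()),
               class = "strokeseg_value_error")
  tc <- train_config()
  expect_equal(tc$learning_rate, 1e-4)
  expect_equal(tc$momentum, 0.9)
  expect_equal(tc$regularization, 5e-4)
  expect_equal(tc$max_iterations, 21000L)
  expect_equal(tc$loss_weights, c(0.8, 0.2))
})

test_that("predict thresholds by argmax with mask values in {0,1}", {
  cfg <- phantom_config(shape = c(16, 16, 1), radius_range = c(3, 5))
  ds <- generate_dataset(cfg, 2, seed = 31)
  m <- build_model(list(channels = names(ds[[1]]$stack), depth = 1,
                        base_channels = 2, seed = 9))
  pr <- predict(m, ds[[1]]$stack)
  expect_true(all(pr$mask$labels %in% c(0L, 1L)))
  p <- pr$probs$probs
  manual <- array(as.integer(p[, , , 2] > p[, , , 1]), dim = dim(p)[1:3])
  expect_identical(pr$mask$labels, manual)
})

test_that("tidy and glance summarize models as tibbles", {
  m <- build_model(list(in_channels = 2, depth = 1, base_channels = 2))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("layer", "n_weights", "bias_max_abs") %in% names(td)))
  expect_true(all(td$bias_max_abs == 0))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$iterations_trained, 0L)
})
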