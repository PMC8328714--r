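# Encoder-decoder segmentation network (2-D, slice-wise) with a centered
# crop layer on skip connections and a dual-weighted auxiliary softmax head.
#
# The forward/backward passes are written out explicitly against the Rcpp
# kernels in src/nn_ops.cpp; the auxiliary head sits on the penultimate
# decoder stage (the bottleneck when depth = 1), is mapped to input
# resolution by nearest upsampling + crop, and contributes to the loss with
# weight 0.2 against 0.8 for the main head.

#' Training configuration
#'
#' Defaults follow the reference training setup: Adam with learning rate
#' 0.0001, first-moment decay (momentum) 0.9, L2 regularization coefficient
#' 0.0005 applied to convolution weights, and a maximum of 21,000
#' iterations. Batch size 8 is the package default.
#'
#' @param learning_rate Positive Adam step size.
#' @param momentum Adam first-moment decay (beta1).
#' @param regularization L2 weight-decay coefficient.
#' @param max_iterations Maximum optimizer steps (>= 1).
#' @param batch_size Minibatch size.
#' @param seed Integer seed fixing minibatch sampling.
#' @param loss_weights Main/auxiliary loss weights (sum to 1).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9,
                         regularization = 5e-4, max_iterations = 21000L,
                         batch_size = 8L, seed = 1L,
                         loss_weights = c(0.8, 0.2)) {
  if (learning_rate < 0) abort("learning_rate must be >= 0",
                               class = "strokeseg_value_error")
  if (max_iterations < 1) abort("max_iterations must be >= 1",
                                class = "strokeseg_value_error")
  if (momentum < 0 || momentum >= 1) abort("momentum must be in [0, 1)",
                                           class = "strokeseg_value_error")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 regularization = regularization,
                 max_iterations = as.integer(max_iterations),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss_weights = loss_weights),
            class = "train_config")
}

enc_channels <- function(base, d) base * 2L^(d - 1L)

#' Build the segmentation network
#'
#' Constructs a symmetric encoder-decoder model: `depth` encoder stages of
#' two 3x3 convolutions (ReLU) plus 2x2 max pooling, a two-convolution
#' bottleneck, and mirrored decoder stages joined to encoder features
#' through nearest upsampling, the crop layer and channel concatenation.
#' Two 1x1-convolution softmax heads produce the main (full-resolution) and
#' auxiliary probability maps. All biases are initialized to zero; weights
#' use seeded He-normal initialization.
#'
#' @param arch_config List with `in_channels` (>= 1), `depth` (>= 1),
#'   `base_channels` (>= 1); optional `input_size` (H, W) to validate that
#'   the spatial dims survive the pooling depth, `channels` (names of the
#'   stack channels the network consumes, in order), and `seed`.
#' @return A `seg_model`.
#' @export
build_model <- function(arch_config) {
  a <- modifyList(list(in_channels = NULL, depth = 2L, base_channels = 8L,
                       n_classes = 2L, input_size = NULL, channels = NULL,
                       normalize = TRUE, seed = 1L),
                  arch_config)
  if (is.null(a$in_channels) && !is.null(a$channels))
    a$in_channels <- length(a$channels)
  if (is.null(a$in_channels) || a$in_channels < 1 || a$depth < 1 ||
      a$base_channels < 1)
    abort("need in_channels >= 1, depth >= 1, base_channels >= 1",
          class = "strokeseg_config_error")
  if (!is.null(a$input_size) && min(a$input_size[1:2]) < 2^a$depth)
    abort("input spatial dims too small for the pooling depth",
          class = "strokeseg_config_error")
  a$depth <- as.integer(a$depth)
  a$base_channels <- as.integer(a$base_channels)
  B <- a$base_channels
  D <- a$depth
  k <- as.integer(a$n_classes)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(a$seed)
  he_conv <- function(kh, kw, cin, cout) {
    sd <- sqrt(2 / (kh * kw * cin))
    list(w = array(rnorm(kh * kw * cin * cout, sd = sd),
                   dim = c(kh, kw, cin, cout)),
         b = numeric(cout))  # zero bias initialization
  }
  params <- list()
  cin <- a$in_channels
  for (d in seq_len(D)) {
    ch <- enc_channels(B, d)
    params[[paste0("enc", d, ".conv1")]] <- he_conv(3, 3, cin, ch)
    params[[paste0("enc", d, ".conv2")]] <- he_conv(3, 3, ch, ch)
    cin <- ch
  }
  chb <- enc_channels(B, D + 1L)
  params[["bot.conv1"]] <- he_conv(3, 3, enc_channels(B, D), chb)
  params[["bot.conv2"]] <- he_conv(3, 3, chb, chb)
  for (d in rev(seq_len(D))) {
    ch <- enc_channels(B, d)
    params[[paste0("dec", d, ".conv1")]] <- he_conv(3, 3, 3L * ch, ch)
    params[[paste0("dec", d, ".conv2")]] <- he_conv(3, 3, ch, ch)
  }
  params[["head.main"]] <- he_conv(1, 1, B, k)
  params[["head.aux"]] <- he_conv(1, 1, 2L * B, k)

  structure(list(arch = a, params = params, iterations_trained = 0L,
                 history = NULL, seed = a$seed),
            class = "seg_model")
}

# forward pass on an (H, W, C, N) array; returns probs and optional cache
unet_forward_array <- function(params, arch, x, keep_cache = FALSE) {
  d0 <- dim(x)
  if (d0[3] != arch$in_channels)
    abort("input channel count does not match model",
          class = "strokeseg_config_error")
  if (min(d0[1:2]) < 2^arch$depth)
    abort("input spatial dims too small for the pooling depth",
          class = "strokeseg_config_error")
  D <- arch$depth
  cache <- list(enc = vector("list", D), dec = vector("list", D))
  h <- x
  skips <- vector("list", D)
  for (d in seq_len(D)) {
    p1 <- params[[paste0("enc", d, ".conv1")]]
    p2 <- params[[paste0("enc", d, ".conv2")]]
    a1 <- relu(nn_conv2d_fwd(h, p1$w, p1$b))
    a2 <- relu(nn_conv2d_fwd(a1, p2$w, p2$b))
    pl <- nn_maxpool2_fwd(a2)
    if (keep_cache) cache$enc[[d]] <- list(x_in = h, a1 = a1, a2 = a2,
                                           idx = pl$idx, a2dim = dim(a2))
    skips[[d]] <- a2
    h <- pl$y
  }
  pb1 <- params[["bot.conv1"]]; pb2 <- params[["bot.conv2"]]
  b1 <- relu(nn_conv2d_fwd(h, pb1$w, pb1$b))
  b2 <- relu(nn_conv2d_fwd(b1, pb2$w, pb2$b))
  if (keep_cache) cache$bot <- list(x_in = h, a1 = b1, a2 = b2)
  h <- b2
  aux_feat <- if (D == 1L) b2 else NULL
  for (d in rev(seq_len(D))) {
    p1 <- params[[paste0("dec", d, ".conv1")]]
    p2 <- params[[paste0("dec", d, ".conv2")]]
    up <- nn_upsample2_fwd(h)
    updim <- dim(up)
    upc <- crop(up, dim(skips[[d]])[1:2])
    cat_in <- concat_channels(upc, skips[[d]])
    a1 <- relu(nn_conv2d_fwd(cat_in, p1$w, p1$b))
    a2 <- relu(nn_conv2d_fwd(a1, p2$w, p2$b))
    if (keep_cache) cache$dec[[d]] <- list(cat_in = cat_in, a1 = a1, a2 = a2,
                                           updim = updim,
                                           ch_below = dim(h)[3])
    h <- a2
    if (d == 2L) aux_feat <- a2
  }
  pm <- params[["head.main"]]; pa <- params[["head.aux"]]
  logit_main <- nn_conv2d_fwd(h, pm$w, pm$b)
  logit_aux <- nn_conv2d_fwd(aux_feat, pa$w, pa$b)
  aux_up <- nn_upsample2_fwd(logit_aux)
  aux_updim <- dim(aux_up)
  aux_logit_full <- crop(aux_up, d0[1:2])
  main_probs <- softmax4(logit_main)
  aux_probs <- softmax4(aux_logit_full)
  if (keep_cache) {
    cache$final <- h
    cache$aux_feat <- aux_feat
    cache$aux_updim <- aux_updim
  }
  list(main = main_probs, aux = aux_probs,
       cache = if (keep_cache) cache else NULL)
}

# backward pass: gradients of 0.8 * CE(main) + 0.2 * CE(aux) w.r.t. params.
# labels: (H, W, N) array over {0, 1}; probs/cache from unet_forward_array.
unet_backward_array <- function(params, arch, fwd, labels, loss_weights) {
  D <- arch$depth
  cache <- fwd$cache
  d0 <- dim(fwd$main)
  H <- d0[1]; W <- d0[2]; N <- d0[4]
  m <- H * W * N
  onehot <- array(0, dim = d0)
  onehot[, , 1, ] <- 1 - labels
  onehot[, , 2, ] <- labels
  grads <- list()
  relu_bwd <- function(da, a) da * (a > 0)

  # main head
  dlog_main <- (fwd$main - onehot) * (loss_weights[1] / m)
  pm <- params[["head.main"]]
  bm <- nn_conv2d_bwd(cache$final, pm$w, dlog_main)
  grads[["head.main"]] <- list(w = bm$dw, b = bm$db)
  g <- bm$dx  # grad w.r.t. final decoder output

  # aux head: softmax at full res, back through crop + upsample + 1x1 conv
  dlog_aux_full <- (fwd$aux - onehot) * (loss_weights[2] / m)
  d_aux_up <- crop_bwd(dlog_aux_full, cache$aux_updim)
  dlog_aux <- nn_upsample2_bwd(d_aux_up)
  pa <- params[["head.aux"]]
  ba <- nn_conv2d_bwd(cache$aux_feat, pa$w, dlog_aux)
  grads[["head.aux"]] <- list(w = ba$dw, b = ba$db)
  d_auxfeat <- ba$dx

  skip_grads <- vector("list", D)
  for (d in seq_len(D)) {  # decoder stages in reverse of forward order
    cc <- cache$dec[[d]]
    p1 <- params[[paste0("dec", d, ".conv1")]]
    p2 <- params[[paste0("dec", d, ".conv2")]]
    dz2 <- relu_bwd(g, cc$a2)
    b2 <- nn_conv2d_bwd(cc$a1, p2$w, dz2)
    dz1 <- relu_bwd(b2$dx, cc$a1)
    b1 <- nn_conv2d_bwd(cc$cat_in, p1$w, dz1)
    grads[[paste0("dec", d, ".conv2")]] <- list(w = b2$dw, b = b2$db)
    grads[[paste0("dec", d, ".conv1")]] <- list(w = b1$dw, b = b1$db)
    cb <- cc$ch_below
    d_upc <- b1$dx[, , seq_len(cb), , drop = FALSE]
    skip_grads[[d]] <- b1$dx[, , cb + seq_len(dim(b1$dx)[3] - cb), ,
                             drop = FALSE]
    g <- nn_upsample2_bwd(crop_bwd(d_upc, cache$dec[[d]]$updim))
    if (d + 1L <= D && d + 1L == 2L) g <- g + d_auxfeat
  }
  if (D == 1L) g <- g + d_auxfeat  # aux head sits on the bottleneck

  # bottleneck
  cb <- cache$bot
  pb1 <- params[["bot.conv1"]]; pb2 <- params[["bot.conv2"]]
  dz2 <- relu_bwd(g, cb$a2)
  b2 <- nn_conv2d_bwd(cb$a1, pb2$w, dz2)
  dz1 <- relu_bwd(b2$dx, cb$a1)
  b1 <- nn_conv2d_bwd(cb$x_in, pb1$w, dz1)
  grads[["bot.conv2"]] <- list(w = b2$dw, b = b2$db)
  grads[["bot.conv1"]] <- list(w = b1$dw, b = b1$db)
  g <- b1$dx

  for (d in rev(seq_len(D))) {
    ce <- cache$enc[[d]]
    p1 <- params[[paste0("enc", d, ".conv1")]]
    p2 <- params[[paste0("enc", d, ".conv2")]]
    d_a2 <- nn_maxpool2_bwd(ce$idx, g, as.integer(ce$a2dim)) + skip_grads[[d]]
    dz2 <- relu_bwd(d_a2, ce$a2)
    b2 <- nn_conv2d_bwd(ce$a1, p2$w, dz2)
    dz1 <- relu_bwd(b2$dx, ce$a1)
    b1 <- nn_conv2d_bwd(ce$x_in, p1$w, dz1)
    grads[[paste0("enc", d, ".conv2")]] <- list(w = b2$dw, b = b2$db)
    grads[[paste0("enc", d, ".conv1")]] <- list(w = b1$dw, b = b1$db)
    g <- b1$dx
  }
  grads
}

# cross-entropy of a (H, W, k, N) probability tensor against 0/1 labels
ce_loss_array <- function(probs, labels, eps = 1e-12) {
  p1 <- as.vector(probs[, , 1, ])
  p2 <- as.vector(probs[, , 2, ])
  t <- as.vector(labels)
  -mean(log(pmax(p1 * (1 - t) + p2 * t, eps)))
}

# pull the network input array (H, W, C, n_slices) out of a modality stack;
# each channel is z-scored per slice so raw scanner units (arbitrary
# magnitude) meet the He-initialized weights at unit scale
stack_to_input <- function(stack, channels = NULL, normalize = TRUE) {
  stopifnot(inherits(stack, "modality_stack"))
  if (is.null(channels)) channels <- names(stack)
  missing <- setdiff(channels, names(stack))
  if (length(missing))
    abort(paste0("stack lacks channels: ", paste(missing, collapse = ", ")),
          class = "strokeseg_config_error")
  d <- dim(stack[[1]]$data)
  x <- array(0, dim = c(d[1], d[2], length(channels), d[3]))
  for (ci in seq_along(channels)) {
    for (z in seq_len(d[3])) {
      sl <- stack[[channels[ci]]]$data[, , z]
      if (normalize) {
        s <- stats::sd(sl)
        sl <- (sl - mean(sl)) / if (s > 1e-12) s else 1
      }
      x[, , ci, z] <- sl
    }
  }
  x
}

model_channels <- function(model, stack) {
  ch <- model$arch$channels
  if (is.null(ch)) {
    if (length(stack) != model$arch$in_channels)
      abort("stack channel count does not match model",
            class = "strokeseg_config_error")
    ch <- names(stack)
  }
  ch
}

#' Run the network forward on a modality stack
#'
#' Each z-slice of the stack is passed through the 2-D network; outputs are
#' reassembled on the input grid. Both returned maps satisfy the per-voxel
#' normalization contract.
#'
#' @param model A `seg_model`.
#' @param stack A [stack_modalities()] whose channels match the model.
#' @return List with `main` and `aux` [probability_map()]s.
#' @export
net_forward <- function(model, stack) {
  stopifnot(inherits(model, "seg_model"))
  ch <- model_channels(model, stack)
  x <- stack_to_input(stack, ch, normalize = isTRUE(model$arch$normalize))
  fwd <- unet_forward_array(model$params, model$arch, x)
  d <- dim(stack[[1]]$data)
  k <- dim(fwd$main)[3]
  to_map <- function(p) {
    out <- array(0, dim = c(d, k))
    for (j in seq_len(k)) out[, , , j] <- p[, , j, ]
    probability_map(out, spacing = stack[[1]]$spacing)
  }
  list(main = to_map(fwd$main), aux = to_map(fwd$aux))
}

#' Segment a modality stack
#'
#' Runs the forward pass and thresholds the main probability map by
#' per-voxel argmax; ties go to background.
#'
#' @param object A `seg_model`.
#' @param stack A [stack_modalities()].
#' @param ... Unused.
#' @return List with `mask` (a [binary_mask()]) and `probs` (the main
#'   [probability_map()]).
#' @export
predict.seg_model <- function(object, stack, ...) {
  maps <- net_forward(object, stack)
  p <- maps$main$probs
  lab <- array(as.integer(p[, , , 2] > p[, , , 1]), dim = dim(p)[1:3])
  list(mask = binary_mask(lab, spacing = maps$main$spacing),
       probs = maps$main)
}

#' Train the segmentation network
#'
#' Minimizes the dual-weighted loss (0.8 main + 0.2 auxiliary softmax
#' cross-entropy) with Adam; L2 regularization is applied to convolution
#' weights (not biases). Minibatches are drawn with a seeded RNG, so a run
#' is reproducible on one device. The training curve is stored on the
#' returned model as a `training_log` tibble.
#'
#' @param model A `seg_model` from [build_model()].
#' @param dataset Non-empty list of phantom samples (or lists with `stack`
#'   and `truth`); every z-slice becomes one training image.
#' @param config A [train_config()].
#' @return The trained `seg_model`.
#' @export
train_network <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(config, "train_config"))
  if (!is.list(dataset) || length(dataset) == 0L)
    abort("dataset must be a non-empty list", class = "strokeseg_value_error")
  ch <- model_channels(model, dataset[[1]]$stack)
  xs <- list(); ys <- list()
  for (s in dataset) {
    xa <- stack_to_input(s$stack, ch,
                         normalize = isTRUE(model$arch$normalize))
    for (z in seq_len(dim(xa)[4])) {
      xs[[length(xs) + 1L]] <- xa[, , , z, drop = FALSE]
      ys[[length(ys) + 1L]] <- s$truth$labels[, , z]
    }
  }
  n <- length(xs)
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]; C <- dim(xs[[1]])[3]
  if (min(H, W) < 2^model$arch$depth)
    abort("input spatial dims too small for the pooling depth",
          class = "strokeseg_config_error")

  params <- model$params
  mstate <- lapply(params, function(p) list(w = array(0, dim(p$w)),
                                            b = numeric(length(p$b))))
  vstate <- lapply(params, function(p) list(w = array(0, dim(p$w)),
                                            b = numeric(length(p$b))))
  beta1 <- config$momentum; beta2 <- 0.999; adam_eps <- 1e-8
  lr <- config$learning_rate; lambda <- config$regularization
  lw <- config$loss_weights
  iters <- config$max_iterations
  log_main <- numeric(iters); log_aux <- numeric(iters)
  log_comb <- numeric(iters)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  bs <- min(config$batch_size, n)
  for (it in seq_len(iters)) {
    idx <- sample.int(n, bs)
    xb <- array(0, dim = c(H, W, C, bs))
    yb <- array(0, dim = c(H, W, bs))
    for (i in seq_len(bs)) {
      xb[, , , i] <- xs[[idx[i]]]
      yb[, , i] <- ys[[idx[i]]]
    }
    fwd <- unet_forward_array(params, model$arch, xb, keep_cache = TRUE)
    lmain <- ce_loss_array(fwd$main, yb)
    laux <- ce_loss_array(fwd$aux, yb)
    log_main[it] <- lmain; log_aux[it] <- laux
    log_comb[it] <- combined_loss(lmain, laux, lw)
    grads <- unet_backward_array(params, model$arch, fwd, yb, lw)
    t_bc <- model$iterations_trained + it
    for (nm in names(params)) {
      gw <- grads[[nm]]$w + lambda * params[[nm]]$w
      gb <- grads[[nm]]$b
      mstate[[nm]]$w <- beta1 * mstate[[nm]]$w + (1 - beta1) * gw
      vstate[[nm]]$w <- beta2 * vstate[[nm]]$w + (1 - beta2) * gw^2
      mstate[[nm]]$b <- beta1 * mstate[[nm]]$b + (1 - beta1) * gb
      vstate[[nm]]$b <- beta2 * vstate[[nm]]$b + (1 - beta2) * gb^2
      mh_w <- mstate[[nm]]$w / (1 - beta1^t_bc)
      vh_w <- vstate[[nm]]$w / (1 - beta2^t_bc)
      mh_b <- mstate[[nm]]$b / (1 - beta1^t_bc)
      vh_b <- vstate[[nm]]$b / (1 - beta2^t_bc)
      params[[nm]]$w <- params[[nm]]$w - lr * mh_w / (sqrt(vh_w) + adam_eps)
      params[[nm]]$b <- params[[nm]]$b - lr * mh_b / (sqrt(vh_b) + adam_eps)
    }
  }
  model$params <- params
  model$iterations_trained <- model$iterations_trained + iters
  hist <- tibble(iteration = seq_len(iters), main_loss = log_main,
                 aux_loss = log_aux, combined_loss = log_comb)
  class(hist) <- c("training_log", class(hist))
  model$history <- if (is.null(model$history)) hist else {
    hist$iteration <- hist$iteration + max(model$history$iteration)
    h <- rbind(as.data.frame(model$history), as.data.frame(hist))
    h <- as_tibble(h); class(h) <- c("training_log", class(h)); h
  }
  model
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params,
                   function(p) length(p$w) + length(p$b), numeric(1)))
  cat("<seg_model> depth ", x$arch$depth, ", base ", x$arch$base_channels,
      " channels, ", x$arch$in_channels, " input channels, ",
      format(np, big.mark = ","), " parameters, trained ",
      x$iterations_trained, " iterations\n", sep = "")
  invisible(x)
}

#' Tidy summary of network parameters
#'
#' @param x A `seg_model`.
#' @param ... Unused.
#' @return A tibble with one row per layer: parameter counts and weight
#'   summary statistics.
#' @export
tidy.seg_model <- function(x, ...) {
  rows <- lapply(names(x$params), function(nm) {
    p <- x$params[[nm]]
    tibble(layer = nm,
           kernel = paste(dim(p$w)[1:2], collapse = "x"),
           in_channels = dim(p$w)[3], out_channels = dim(p$w)[4],
           n_weights = length(p$w), n_biases = length(p$b),
           weight_sd = stats::sd(p$w), bias_max_abs = max(abs(p$b)))
  })
  do.call(rbind, rows)
}

#' One-row model summary
#'
#' @param x A `seg_model`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, parameter count, iterations
#'   trained and final losses (NA if untrained).
#' @export
glance.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params,
                   function(p) length(p$w) + length(p$b), numeric(1)))
  h <- x$history
  tibble(depth = x$arch$depth, base_channels = x$arch$base_channels,
         in_channels = x$arch$in_channels, n_parameters = np,
         iterations_trained = x$iterations_trained,
         final_main_loss = if (is.null(h)) NA_real_ else h$main_loss[nrow(h)],
         final_combined_loss = if (is.null(h)) NA_real_
                               else h$combined_loss[nrow(h)])
}
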