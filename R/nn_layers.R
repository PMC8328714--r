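# Network primitives: softmax normalization, the multinomial (softmax
# cross-entropy) loss, the dual-weighted combined loss and the centered
# crop layer.

#' Softmax normalization
#'
#' Maps per-class real scores to positive probabilities that sum to 1.
#' Computed with the max-shift for numerical stability; shift invariance is
#' exact in exact arithmetic.
#'
#' @param logits Numeric vector of per-class scores (finite).
#' @return Probability vector of the same length.
#' @examples
#' softmax(c(1, 2, 3))
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 2L)
    abort("need at least two class scores", class = "strokeseg_value_error")
  if (any(!is.finite(logits)))
    abort("logits must be finite", class = "strokeseg_value_error")
  e <- exp(logits - max(logits))
  e / sum(e)
}

# softmax over the class dim (3rd) of an (H, W, k, N) logit tensor;
# max-shifted, written slice-wise to stay vectorized
softmax4 <- function(logits) {
  d <- dim(logits)
  k <- d[3]
  mx <- logits[, , 1, ]
  for (j in seq_len(k)[-1]) mx <- pmax(mx, logits[, , j, ])
  es <- vector("list", k)
  s <- 0
  for (j in seq_len(k)) {
    es[[j]] <- exp(logits[, , j, ] - mx)
    s <- s + es[[j]]
  }
  out <- array(0, dim = d)
  for (j in seq_len(k)) out[, , j, ] <- es[[j]] / s
  out
}

#' Multinomial (softmax cross-entropy) loss
#'
#' `J = -(1/m) * sum_i log p_i(d_i)`: the average negative log-probability
#' assigned to the true class. Zero for perfect one-hot predictions.
#' Probabilities are clamped at `eps` so the loss is never infinite.
#'
#' @param probs Numeric matrix `m x k` of class probabilities per sample
#'   (rows sum to 1), or a vector treated as a 1-sample matrix.
#' @param labels Integer class indices in `1..k`, length `m`.
#' @param eps Clamping floor for log probabilities.
#' @return Non-negative scalar loss.
#' @examples
#' multinomial_loss(matrix(c(0.5, 0.5), 1), 1)  # ln 2
#' @export
multinomial_loss <- function(probs, labels, eps = 1e-12) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  m <- nrow(probs)
  k <- ncol(probs)
  labels <- as.integer(labels)
  if (length(labels) != m || any(labels < 1L) || any(labels > k))
    abort("labels must be class indices in 1..k, one per sample",
          class = "strokeseg_value_error")
  p <- probs[cbind(seq_len(m), labels)]
  -sum(log(pmax(p, eps))) / m
}

#' Dual-weighted combined loss
#'
#' Convex combination of the main and auxiliary segmentation losses with
#' weights 0.8 and 0.2.
#'
#' @param main_loss,aux_loss Non-negative loss values.
#' @param weights Length-2 non-negative weights summing to 1.
#' @return `weights[1] * main_loss + weights[2] * aux_loss`.
#' @examples
#' combined_loss(1.0, 0.5)  # 0.9
#' @export
combined_loss <- function(main_loss, aux_loss, weights = c(0.8, 0.2)) {
  if (main_loss < 0 || aux_loss < 0)
    abort("losses must be non-negative", class = "strokeseg_value_error")
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    abort("weights must be two non-negative values summing to 1",
          class = "strokeseg_value_error")
  weights[1] * main_loss + weights[2] * aux_loss
}

#' Centered spatial crop
#'
#' Crops the two leading spatial dimensions of a feature map to a target
#' shape, keeping the central window; channel (and batch) dimensions are
#' untouched. This is the network's clipping layer: it aligns decoder
#' feature maps with encoder skip connections so images of any size can be
#' segmented.
#'
#' @param x Array with spatial dims first: `(H, W)`, `(H, W, C)` or
#'   `(H, W, C, N)`.
#' @param target_shape Integer `(H', W')` with `H' <= H`, `W' <= W`.
#' @return The cropped array.
#' @export
crop <- function(x, target_shape) {
  d <- dim(x)
  if (is.null(d)) abort("x must be an array", class = "strokeseg_dim_error")
  target_shape <- as.integer(target_shape[1:2])
  if (any(target_shape > d[1:2]))
    abort("crop target larger than source", class = "strokeseg_shape_error")
  off <- floor((d[1:2] - target_shape) / 2)
  hidx <- seq.int(off[1] + 1L, off[1] + target_shape[1])
  widx <- seq.int(off[2] + 1L, off[2] + target_shape[2])
  if (length(d) == 2L) x[hidx, widx, drop = FALSE]
  else if (length(d) == 3L) x[hidx, widx, , drop = FALSE]
  else if (length(d) == 4L) x[hidx, widx, , , drop = FALSE]
  else abort("unsupported array rank", class = "strokeseg_dim_error")
}

# gradient of crop: embed dy back into an array of the source shape
crop_bwd <- function(dy, source_shape) {
  d <- dim(dy)
  out <- array(0, dim = c(source_shape[1:2], d[-(1:2)]))
  off <- floor((source_shape[1:2] - d[1:2]) / 2)
  hidx <- seq.int(off[1] + 1L, off[1] + d[1])
  widx <- seq.int(off[2] + 1L, off[2] + d[2])
  if (length(d) == 4L) out[hidx, widx, , ] <- dy
  else if (length(d) == 3L) out[hidx, widx, ] <- dy
  else out[hidx, widx] <- dy
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# channel-wise concatenation of (H, W, C, N) tensors
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
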