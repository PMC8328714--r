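# ggplot2 visualisation helpers.

#' Plot a training curve
#'
#' @param object A `training_log` tibble (the `history` element of a
#'   trained model).
#' @param ... Unused.
#' @return A ggplot: main, auxiliary and combined loss against iteration.
#' @export
autoplot.training_log <- function(object, ...) {
  df <- data.frame(
    iteration = rep(object$iteration, 3),
    loss = c(object$main_loss, object$aux_loss, object$combined_loss),
    head = rep(c("main", "auxiliary", "combined"),
               each = nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                   colour = .data$head)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "softmax cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one axial slice of a volume, mask or probability map
#'
#' @param x A [volume3d()], [binary_mask()] or [probability_map()] (lesion
#'   class shown).
#' @param z Slice index.
#' @param overlay Optional [binary_mask()] drawn as a contour on top.
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(x, z = 1L, overlay = NULL) {
  sl <- if (inherits(x, "volume3d")) x$data[, , z]
  else if (inherits(x, "binary_mask")) x$labels[, , z]
  else if (inherits(x, "prob_map")) x$probs[, , z, dim(x$probs)[4]]
  else abort("unsupported object", class = "strokeseg_value_error")
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(overlay)) {
    od <- expand.grid(x = seq_len(dim(overlay$labels)[1]),
                      y = seq_len(dim(overlay$labels)[2]))
    od$value <- as.vector(overlay$labels[, , z])
    p <- p + ggplot2::geom_contour(data = od,
                                   mapping = ggplot2::aes(x = .data$x,
                                                          y = .data$y,
                                                          z = .data$value),
                                   breaks = 0.5, colour = "red",
                                   inherit.aes = FALSE)
  }
  p
}

#' @importFrom rlang .data
NULL
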