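# ggplot2 visualisations of the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_to_long <- function(image) {
  tibble::tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    intensity = as.vector(image)
  )
}

#' Plot a phantom with its ground truth overlaid
#'
#' @param object A [generate_phantom()] result.
#' @param ... Unused.
#' @return A ggplot: the intensity raster with the true ROI box and
#'   joint-space mask outline.
#' @method autoplot knee_phantom
#' @export
autoplot.knee_phantom <- function(object, ...) {
  df <- image_to_long(object$image)
  mask_df <- image_to_long(object$true_mask * 1)
  mask_df <- mask_df[mask_df$intensity > 0, ]
  roi <- object$true_roi
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_tile(data = mask_df, fill = "red", alpha = 0.25) +
    ggplot2::annotate("rect",
                      xmin = roi$col_start + 0.5, xmax = roi$col_end + 0.5,
                      ymin = roi$row_start + 0.5, ymax = roi$row_end + 0.5,
                      colour = "cyan", fill = NA, linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Knee phantom (grade %s)",
                                  as.character(object$grade)),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Heatmap of a KL confusion matrix
#'
#' @param object A [as_kl_confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot tile map, rows = predicted, columns = expert grades.
#' @method autoplot kl_confusion
#' @export
autoplot.kl_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("predicted", "expert", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expert, y = .data$predicted)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(kl_grades())) +
    ggplot2::labs(x = "Expert annotation", y = "Algorithm prediction",
                  fill = "count") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kl_confusion
#' @method autoplot kl_cv
#' @export
autoplot.kl_cv <- function(object, ...) {
  autoplot(object$confusion) +
    ggplot2::labs(title = sprintf("%s, pooled 2-fold CV accuracy %.4f",
                                  object$classifier, object$accuracy))
}

#' Scatter the labelled Hu feature space
#'
#' @param features Tibble from [generate_feature_dataset()].
#' @param x,y Feature columns to plot (defaults `phi1`, `phi2`).
#' @return A ggplot scatter of the two invariants coloured by KL grade.
#' @export
plot_feature_space <- function(features, x = "phi1", y = "phi2") {
  if (!all(c(x, y, "grade") %in% names(features))) {
    stop_invalid("`features` must contain the requested columns and `grade`")
  }
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data[[x]], y = .data[[y]],
                               colour = .data$grade)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "KL grade") +
    ggplot2::theme_minimal()
}
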