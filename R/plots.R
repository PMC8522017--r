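# ggplot2 displays for trend matrices, category profiles and count fits.

#' Heatmap of a temporal trend matrix
#'
#' Time bins on the x axis, topics (sorted by descending overall
#' proportion) on the y axis, fill by topic proportion.  The `"bilinear"`
#' scale applies a two-segment linear color mapping with a breakpoint
#' (default: the matrix median) that spreads color resolution across the
#' many small proportions; it changes rendering only, never the data.
#'
#' @param object a [trend_matrix()].
#' @param scale `"linear"` or `"bilinear"`.
#' @param breakpoint fill value at the color-scale midpoint for
#'   `"bilinear"` (default `median(theta)`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot trend_matrix
#' @export
autoplot.trend_matrix <- function(object, scale = c("linear", "bilinear"),
                                  breakpoint = NULL, ...) {
  scale <- match.arg(scale)
  ord <- topic_display_order(object)
  df <- tidy(object)
  df$topic <- factor(df$topic, levels = rev(ord))
  df$bin <- factor(df$bin, levels = object$bins$label)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$topic,
                                        fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "time bin", y = "topic", fill = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (scale == "bilinear") {
    if (is.null(breakpoint)) breakpoint <- stats::median(object$theta)
    lim <- range(object$theta)
    mid <- (breakpoint - lim[1]) / diff(lim)
    p <- p + ggplot2::scale_fill_gradientn(
      colours = c("#132B43", "#3E78B2", "#F6E8C3", "#D73027"),
      values = c(0, mid, mid + (1 - mid) / 2, 1), limits = lim)
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Heatmap of max-normalized category topic profiles
#'
#' @param object a [category_profiles()] result.
#' @param normalized plot the max-normalized proportions (default TRUE) or
#'   the raw topic proportions.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot category_profiles
#' @export
autoplot.category_profiles <- function(object, normalized = TRUE, ...) {
  df <- tibble::as_tibble(object)
  fill_var <- if (normalized) "norm_proportion" else "proportion"
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$topic),
                                   y = .data$category,
                                   fill = .data[[fill_var]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "topic", y = "category",
                  fill = if (normalized) "proportion /\nmax" else "proportion") +
    ggplot2::theme_minimal()
}

#' Weekly counts with the fitted Gaussian curve
#'
#' @param object a [fit_gaussian_counts()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gaussian_fit
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linetype = "dashed", linewidth = 0.8) +
    ggplot2::labs(x = "bin midpoint", y = "documents") +
    ggplot2::theme_minimal()
}

#' Labelled Hellinger distance heatmap
#'
#' @param m a labelled symmetric matrix from [hellinger_matrix()].
#' @return A ggplot object.
#' @export
plot_hellinger_matrix <- function(m) {
  df <- tibble::tibble(
    row = rep(rownames(m), times = ncol(m)),
    col = rep(colnames(m), each = nrow(m)),
    distance = as.vector(m))
  df$row <- factor(df$row, levels = rev(rownames(m)))
  df$col <- factor(df$col, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$distance)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hellinger") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
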