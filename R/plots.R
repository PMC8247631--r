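#' Plot an instance set over its image
#'
#' Draws the image as a raster with object outlines (or fills) coloured by
#' label.
#'
#' @param s an [instance_set()].
#' @param image optional background intensity matrix.
#' @param alpha fill transparency for objects.
#' @return a ggplot object.
#' @export
plot_instances <- function(s, image = NULL, alpha = 0.4) {
  td <- tidy(s)
  layers <- list()
  if (!is.null(image)) {
    img_df <- tibble::tibble(
      row = rep(seq_len(nrow(image)), times = ncol(image)),
      col = rep(seq_len(ncol(image)), each = nrow(image)),
      value = as.vector(image)
    )
    layers <- c(layers, list(
      ggplot2::geom_raster(
        data = img_df,
        ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)
      ),
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
    ))
  }
  px <- purrr::map2_dfr(s$objects, s$labels, function(p, lb) {
    tibble::tibble(
      row = (p - 1L) %% s$dim[1] + 1L,
      col = (p - 1L) %/% s$dim[1] + 1L,
      label = factor(lb)
    )
  })
  ggplot2::ggplot() +
    layers +
    ggplot2::geom_tile(
      data = px,
      ggplot2::aes(x = .data$col, y = .data$row, colour = .data$label),
      alpha = alpha, linewidth = 0
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-threshold score curves of a match table
#'
#' @param object a `match_table` from [match_objects()].
#' @param ... unused.
#' @return a ggplot of TP/FP/FN against the IoU threshold.
#' @export
autoplot.match_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("tp", "fp", "fn"),
                              names_to = "count", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$n,
                                     colour = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IoU threshold", y = "objects", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-image score distributions of a score report
#'
#' @param object a `score_report` from [score_set()].
#' @param ... unused.
#' @return a ggplot of per-image metric values.
#' @export
autoplot.score_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("dsb", "map", "mar", "mf1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' GA fitness trajectory
#'
#' @param object a `pp_fit` from [optimize_params()].
#' @param ... unused.
#' @return a ggplot of best/mean fitness per generation.
#' @export
autoplot.pp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("best", "mean"),
                              names_to = "which", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "mean DSB score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
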