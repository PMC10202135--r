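# ggplot2 views of the package's result types.

#' Plot a rendered frame
#'
#' @param object A `rendered_frame`.
#' @param annotations Optional annotation or detection tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rendered_frame <- function(object, annotations = NULL, ...) {
  rgb <- pmin(pmax(object$rgb, 0), 1)^(1 / 2.2)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  df <- tibble(
    u = rep(0:(W - 1), each = H),
    v = rep(0:(H - 1), times = W),
    col = grDevices::rgb(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                         as.vector(rgb[, , 3])))
  p <- ggplot(df, aes(x = .data$u, y = .data$v)) +
    geom_raster(aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    scale_y_reverse() + coord_equal(expand = FALSE) +
    labs(x = "u (px)", y = "v (px)") + theme_minimal()
  if (!is.null(annotations) && nrow(annotations) > 0)
    p <- p + geom_point(data = annotations,
                        aes(x = .data$center_u, y = .data$center_v),
                        colour = "red", shape = 3, size = 2)
  p
}

#' Plot a per-stage evaluation report
#'
#' @param object A `tip_eval` from [per_stage_report()].
#' @param ... Unused.
#' @return A ggplot with one panel per metric across stage bins.
#' @export
autoplot.tip_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_stage,
                            c("precision", "recall", "mae", "rmse"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$stage, y = .data$value)) +
    geom_col(fill = "seagreen") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Haun stage bin", y = NULL,
         title = "Leaf-tip detection by development stage") +
    theme_minimal()
}

#' Plot an experiment table
#'
#' Resolution sweeps (a `gsd` column) are drawn as metric-vs-GSD lines;
#' realism ablations as per-condition columns.
#'
#' @param object An `experiment_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_table <- function(object, ...) {
  if ("gsd" %in% names(object)) {
    df <- tidyr::pivot_longer(object, c("mae", "rmse"),
                              names_to = "metric", values_to = "value")
    ggplot(df, aes(x = .data$gsd, y = .data$value,
                   colour = .data$metric)) +
      geom_line() + geom_point() +
      labs(x = "Ground sampling distance (mm/px)", y = "Counting error",
           title = "Counting accuracy vs spatial resolution") +
      theme_minimal()
  } else {
    df <- tidyr::pivot_longer(object, c("rmse", "distance"),
                              names_to = "metric", values_to = "value")
    ggplot(df, aes(x = .data$condition, y = .data$value)) +
      geom_col(fill = "steelblue") +
      facet_wrap(~metric, scales = "free_y") +
      labs(x = "Varied realism factors", y = NULL,
           title = "Realism-factor ablation") +
      theme_minimal()
  }
}

#' Plot a joint 2-D embedding of two datasets
#'
#' @param embedding Tibble from [embed_2d()] on the stacked features.
#' @param groups Factor/character vector labelling each row's dataset.
#' @return A ggplot.
#' @export
plot_gap_embedding <- function(embedding, groups) {
  df <- mutate(embedding, dataset = groups)
  ggplot(df, aes(x = .data$dim1, y = .data$dim2,
                 colour = .data$dataset)) +
    geom_point(alpha = 0.8) +
    labs(title = "Feature-space embedding of the two datasets") +
    theme_minimal()
}
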