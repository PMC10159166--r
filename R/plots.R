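#' Reporting plots for the pipeline results
#'
#' Lightweight ggplot2 figures mirroring the standard diagnostics of the
#' benchmark: data retention versus the IQR multiplier, the PCA scree
#' curve, per-class feature histograms, the ensemble-average confusion
#' heatmap, metric histograms and pairwise metric scatterplots.
#'
#' @param retention named vector from [retention_curve()].
#' @return a ggplot object.
#' @name pipeline_plots
NULL

#' @rdname pipeline_plots
#' @export
plot_retention_curve <- function(retention) {
  df <- data.frame(n = as.numeric(names(retention)),
                   retained = as.numeric(retention))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$retained)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IQR multiplier n", y = "fraction of rows retained") +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @param model a [fit_pca()] model.
#' @param threshold cumulative-variance threshold drawn as a reference.
#' @export
plot_scree <- function(model, threshold = 0.9) {
  df <- data.frame(component = seq_along(model$ratios),
                   cumulative = cumsum(model$ratios))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "principal component",
                  y = "cumulative explained variance") +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @param table a feature table.
#' @param by label column to colour by (`"stimulus"` or `"species"`).
#' @param bins histogram bins.
#' @export
plot_feature_histograms <- function(table, by = "stimulus", bins = 40) {
  feats <- feature_columns(table)
  long <- do.call(rbind, lapply(feats, function(f) {
    data.frame(feature = f, value = table[[f]], group = table[[by]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.5) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, fill = by) +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @param C ensemble-average row-normalized confusion matrix
#'   (see [average_confusion()]).
#' @export
plot_confusion <- function(C) {
  df <- expand.grid(true = rownames(C), pred = colnames(C))
  df$rate <- as.numeric(C)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(C))) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @param metrics named list of [metric_distributions()] per space, e.g.
#'   `list("15d" = md15, "7d" = md7)` for one classifier.
#' @param metric which metric column to plot.
#' @export
plot_metric_distributions <- function(metrics, metric = "bal_acc",
                                      bins = 30) {
  long <- do.call(rbind, lapply(names(metrics), function(space) {
    data.frame(space = space, value = metrics[[space]][[metric]])
  }))
  means <- vapply(split(long$value, long$space), mean, numeric(1))
  ttl <- paste(sprintf("%s mean %.3f", names(means), means), collapse = "; ")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$space)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = metric, title = ttl) +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @param mx,my metric column names for the x and y axes of the pairwise
#'   scatterplot.
#' @export
plot_metric_scatter <- function(metrics, mx = "f1", my = "mcc") {
  long <- do.call(rbind, lapply(names(metrics), function(space) {
    data.frame(space = space, x = metrics[[space]][[mx]],
               y = metrics[[space]][[my]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$space)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = mx, y = my) +
    ggplot2::theme_minimal()
}
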