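# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text labs scale_fill_gradient theme_minimal facet_wrap
NULL

#' Plot an ECG record
#'
#' Signal trace with the annotated R peaks marked.
#'
#' @param object An `ecg_record`.
#' @param window Optional numeric length-2 window in seconds to restrict the
#'   display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, window = NULL, ...) {
  df <- tidy.ecg_record(object)
  peaks <- tibble(time_s = (object$rpeaks - 1) / object$fs,
                  mv = object$signal[object$rpeaks],
                  label = object$labels)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time_s >= window[1], .data$time_s <= window[2])
    peaks <- dplyr::filter(peaks, .data$time_s >= window[1],
                           .data$time_s <= window[2])
  }
  p <- ggplot(df, aes(x = .data$time_s, y = .data$mv)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "amplitude (mV)",
         title = object$record_id %||% "ECG record") +
    theme_minimal()
  if (nrow(peaks)) {
    p <- p + geom_point(data = peaks, aes(colour = .data$label), size = 1.5) +
      labs(colour = "AAMI class")
  }
  p
}

#' Plot a confusion matrix
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot heatmap of the confusion counts.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "prediction", "count")
  ggplot(df, aes(x = .data$prediction, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = sprintf("Accuracy %.3f", object$accuracy)) +
    theme_minimal()
}

#' Plot a training history
#'
#' @param object A `beat_classifier`.
#' @param ... Unused.
#' @return A ggplot of per-epoch training loss and accuracy.
#' @export
autoplot.beat_classifier <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~metric, scales = "free_y") +
    labs(title = sprintf("%s training history", object$spec$name)) +
    theme_minimal()
}

#' Plot class-mean feature rows
#'
#' Displays the per-class mean of the feature columns, a quick visual check
#' of inter-class separation.
#'
#' @param features A labelled `beat_features` tibble.
#' @return A ggplot object.
#' @export
plot_class_means <- function(features) {
  X <- feature_matrix(features)
  df <- dplyr::bind_rows(lapply(split(seq_len(nrow(X)), features$label),
                                function(idx) {
    if (length(idx) == 0) return(NULL)
    tibble(position = seq_len(ncol(X)), value = colMeans(X[idx, , drop = FALSE]))
  }), .id = "class")
  ggplot(df, aes(x = .data$position, y = .data$value, colour = .data$class)) +
    geom_line() +
    labs(x = "feature position", y = "mean value", colour = "AAMI class") +
    theme_minimal()
}
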