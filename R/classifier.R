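# User-facing training and evaluation around the network engine: stratified
# splitting, one-hot targets, per-beat class posteriors, confusion-matrix
# metrics.

#' Fit a heartbeat classifier
#'
#' Trains one of the three architectures on a labelled feature table.
#' Beats are split into stratified train/test subsets (70/30 by default) at
#' the configured seed, targets are one-hot encoded, and the network is
#' optimised with Adam on categorical cross-entropy. Stratification keeps
#' rare classes (the Q class can be a handful of beats) represented on both
#' sides of the split; a class absent from the training split triggers a
#' warning but stays in the output space.
#'
#' @param features A labelled `beat_features` tibble.
#' @param spec An `arch_spec`; its input length must match the feature
#'   width.
#' @param config A [train_config()].
#' @return An object of class `beat_classifier` with the trained network,
#'   training history, split indices and held-out test data.
#' @export
fit_beat_classifier <- function(features, spec,
                                config = train_config()) {
  X <- feature_matrix(features)
  y <- as_aami_factor(features$label)
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- droplevels(y[ok])
  if (nlevels(y) < 2) {
    stop_ecg("Need at least two classes to train a classifier.",
             class = "ecgbeat_validation_error")
  }
  if (ncol(X) != spec$input_length) {
    stop_ecg(sprintf("Feature width %d does not match the architecture input length %d.",
                     ncol(X), spec$input_length),
             class = "ecgbeat_validation_error")
  }
  classes <- aami_classes()[aami_classes() %in% levels(y)]
  y <- factor(as.character(y), levels = classes)
  if (spec$n_classes != length(classes)) {
    spec <- switch(spec$name,
      lstm_sequential = lstm_sequential_spec(spec$input_length,
        spec$layers$config[[2]]$units, length(classes)),
      bilstm = bilstm_spec(spec$input_length,
        spec$layers$config[[2]]$units, length(classes)),
      lstm_fcn = lstm_fcn_spec(spec$input_length,
        spec$layers$config[[which(spec$layers$layer == "lstm")]]$units,
        length(classes)))
  }
  split <- stratified_split(y, config$train_fraction, config$seed)
  if (length(setdiff(classes, as.character(unique(y[split$train]))))) {
    warn("A class is absent from the training split; it is kept in the output space.")
  }
  Y <- diag(length(classes))[as.integer(y), , drop = FALSE]
  fit <- nn_fit(spec, X[split$train, , drop = FALSE],
                Y[split$train, , drop = FALSE], config)
  structure(
    list(net = fit$net, spec = spec, classes = classes, config = config,
         history = fit$history, split = split,
         feature_kind = feature_kind(features),
         feature_names = colnames(X),
         test_x = X[split$test, , drop = FALSE],
         test_y = y[split$test]),
    class = "beat_classifier")
}

stratified_split <- function(y, train_fraction, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_train <- max(1L, round(length(idx) * train_fraction))
      n_train <- min(n_train, length(idx))
      train <- c(train, sample(idx, n_train))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

#' @export
print.beat_classifier <- function(x, ...) {
  cat(sprintf("<beat_classifier %s on %s features: %s parameters, %d epochs>\n",
              x$spec$name, x$feature_kind %||% "?",
              format(parameter_count(x$spec), big.mark = ","),
              nrow(x$history)))
  invisible(x)
}

#' Predict beat classes
#'
#' @param object A `beat_classifier`.
#' @param new_data A `beat_features` tibble or numeric matrix; `NULL` uses
#'   the held-out test split.
#' @param type `"prob"` for class posteriors plus the hard label, `"class"`
#'   for the hard label only.
#' @param batch_size Forward-pass batch size (use 1 to mirror the streaming
#'   export contract).
#' @param ... Unused.
#' @return A tibble with `.pred_class` and, for `type = "prob"`, one
#'   `.pred_<class>` column per class; rows align with `new_data`.
#' @export
predict.beat_classifier <- function(object, new_data = NULL,
                                    type = c("prob", "class"),
                                    batch_size = 1024L, ...) {
  type <- match.arg(type)
  X <- if (is.null(new_data)) object$test_x
       else if (is.matrix(new_data)) new_data
       else feature_matrix(new_data)
  P <- nn_predict_proba(object$net, X, batch_size)
  colnames(P) <- paste0(".pred_", object$classes)
  cls <- factor(object$classes[max.col(P, ties.method = "first")],
                levels = aami_classes())
  out <- tibble(.pred_class = cls)
  if (type == "prob") out <- dplyr::bind_cols(out, as_tibble(P))
  out
}

#' Evaluate a classifier on labelled beats
#'
#' Builds the confusion matrix of true versus predicted classes and derives
#' overall accuracy, support-weighted precision/recall/F1 (macro averages
#' are reported alongside), and per-class accuracy, defined as the per-class
#' recall (diagonal over row sum), the only per-class scalar a single
#' confusion matrix supports.
#'
#' @param model A `beat_classifier`.
#' @param features Labelled `beat_features`; `NULL` evaluates the held-out
#'   test split.
#' @return An `eval_report` object; see [eval_report()].
#' @export
evaluate_classifier <- function(model, features = NULL) {
  if (is.null(features)) {
    X <- model$test_x; y <- model$test_y
  } else {
    X <- feature_matrix(features); y <- as_aami_factor(features$label)
  }
  if (length(y) == 0) {
    stop_ecg("Empty evaluation set.", class = "ecgbeat_validation_error")
  }
  pred <- predict(model, X, type = "class")$.pred_class
  lv <- model$classes
  confusion <- table(truth = factor(as.character(y), levels = lv),
                     prediction = factor(as.character(pred), levels = lv))
  eval_report(unclass(as.matrix(confusion)))
}

#' Classification metrics from a confusion matrix
#'
#' @param confusion Square count matrix, rows = truth, columns = prediction,
#'   identically named.
#' @return An object of class `eval_report`: the confusion matrix plus
#'   accuracy, weighted and macro precision/recall/F1, and per-class recall.
#' @export
eval_report <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop_ecg("`confusion` must be square.", class = "ecgbeat_validation_error")
  }
  total <- sum(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  tp <- diag(confusion)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall /
                 (precision + recall), 0)
  w <- support / total
  wmean <- function(v) sum(ifelse(is.na(v), 0, v) * w)
  present <- support > 0
  structure(
    list(confusion = confusion,
         accuracy = sum(tp) / total,
         precision = wmean(precision), recall = wmean(recall),
         f1 = wmean(f1),
         macro_precision = mean(precision[present]),
         macro_recall = mean(recall[present]),
         macro_f1 = mean(f1[present]),
         per_class = tibble(class = rownames(confusion) %||%
                              as.character(seq_len(nrow(confusion))),
                            support = as.integer(support),
                            precision = precision, recall = recall, f1 = f1,
                            class_accuracy = recall)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f (weighted)>\n",
              x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per class: support, precision, recall, F1
#'   and class accuracy (= recall).
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with accuracy and the weighted and macro-averaged
#'   precision, recall and F1.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f1 = x$f1, macro_precision = x$macro_precision,
         macro_recall = x$macro_recall, macro_f1 = x$macro_f1)
}

#' Tidy a classifier's training history
#'
#' @param x A `beat_classifier`.
#' @param ... Unused.
#' @return A tibble with per-epoch training loss and accuracy.
#' @export
tidy.beat_classifier <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `beat_classifier`.
#' @param ... Unused.
#' @return A tibble with the architecture name, feature kind, parameter
#'   count, epochs run, final training loss and held-out test accuracy.
#' @export
glance.beat_classifier <- function(x, ...) {
  rep <- evaluate_classifier(x)
  tibble(architecture = x$spec$name, feature_kind = x$feature_kind %||% NA,
         n_parameters = parameter_count(x$spec),
         epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         test_accuracy = rep$accuracy)
}
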