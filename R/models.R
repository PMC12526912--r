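# Declarative architecture specifications for the three classifier networks,
# with closed-form per-layer parameter counts.
#
# Counting rules (u = units, d = input dim per timestep, k = kernel width):
#   lstm         4 * (u * (u + d) + u)        single-bias convention
#   bilstm       2 * lstm count
#   dense        in * out + out
#   conv1d       in_ch * k * filters + filters
#   batchnorm    4 * channels                  (scale, shift, running mean/var)
#   everything else 0

layer_param_count <- function(kind, cfg) {
  switch(kind,
    lstm = 4 * (cfg$units * (cfg$units + cfg$input_dim) + cfg$units),
    bilstm = 2 * 4 * (cfg$units * (cfg$units + cfg$input_dim) + cfg$units),
    dense = cfg$in_dim * cfg$units + cfg$units,
    conv1d = cfg$in_channels * cfg$kernel * cfg$filters + cfg$filters,
    batchnorm = 4 * cfg$channels,
    input = , permute = , relu = , dropout = , global_avg_pool = , concat = 0,
    stop_ecg(sprintf("Unknown layer kind '%s'.", kind),
             class = "ecgbeat_validation_error")
  )
}

new_arch_spec <- function(name, input_length, n_classes, layers) {
  layers$param_count <- vapply(seq_len(nrow(layers)), function(i) {
    layer_param_count(layers$kind[i], layers$config[[i]])
  }, numeric(1))
  structure(list(name = name, input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes), layers = layers),
            class = "arch_spec")
}

layer_row <- function(layer, kind, output, input = NA_character_, ...) {
  tibble(layer = layer, kind = kind, output = output, input = input,
         config = list(list(...)))
}

#' LSTM-Sequential architecture
#'
#' A single LSTM layer over the feature sequence, a 128-unit tanh dense
#' layer, and a softmax output over the five beat classes. The default
#' 256-unit variant is the "LSTM-256" model; `lstm_units = 512` gives the
#' "LSTM-512" variant.
#'
#' @param input_length Timesteps of the input sequence (9 for RR features).
#' @param lstm_units LSTM state size.
#' @param n_classes Number of output classes.
#' @return An `arch_spec` object.
#' @export
lstm_sequential_spec <- function(input_length = 9L, lstm_units = 256L,
                                 n_classes = 5L) {
  layers <- dplyr::bind_rows(
    layer_row("input", "input", sprintf("(None, %d, 1)", input_length)),
    layer_row("lstm", "lstm", sprintf("(None, %d)", lstm_units),
              units = lstm_units, input_dim = 1L),
    layer_row("dense_1", "dense", "(None, 128)", units = 128L,
              in_dim = lstm_units, activation = "tanh"),
    layer_row("dense_2", "dense", sprintf("(None, %d)", n_classes),
              units = n_classes, in_dim = 128L, activation = "softmax"))
  new_arch_spec("lstm_sequential", input_length, n_classes, layers)
}

#' Bidirectional LSTM architecture
#'
#' A bidirectional wrapper around an LSTM layer (states of the forward and
#' backward passes concatenated), a 256-unit tanh dense layer, and a softmax
#' output.
#'
#' @inheritParams lstm_sequential_spec
#' @return An `arch_spec` object.
#' @export
bilstm_spec <- function(input_length = 9L, lstm_units = 256L, n_classes = 5L) {
  layers <- dplyr::bind_rows(
    layer_row("input", "input", sprintf("(None, %d, 1)", input_length)),
    layer_row("bidirectional", "bilstm", sprintf("(None, %d)", 2 * lstm_units),
              units = lstm_units, input_dim = 1L),
    layer_row("dense_1", "dense", "(None, 256)", units = 256L,
              in_dim = 2L * lstm_units, activation = "tanh"),
    layer_row("dense_2", "dense", sprintf("(None, %d)", n_classes),
              units = n_classes, in_dim = 256L, activation = "softmax"))
  new_arch_spec("bilstm", input_length, n_classes, layers)
}

#' LSTM-FCN architecture
#'
#' Two branches from the same input: a small LSTM over the raw sequence
#' followed by heavy dropout, and a convolutional stack applied after a
#' dimension permutation (so the timesteps become channels of a length-1
#' sequence): Conv1D(128, k = 8) - BN - ReLU - Conv1D(256, k = 5) - BN -
#' ReLU - Conv1D(128, k = 3) - BN - ReLU - global average pooling. The
#' branch outputs are concatenated and fed to a softmax dense layer.
#'
#' @param input_length Timesteps of the input sequence.
#' @param lstm_units LSTM state size of the recurrent branch.
#' @param n_classes Number of output classes.
#' @param dropout Dropout rate of the recurrent branch.
#' @return An `arch_spec` object.
#' @export
lstm_fcn_spec <- function(input_length = 100L, lstm_units = 8L,
                          n_classes = 5L, dropout = 0.8) {
  L <- input_length
  layers <- dplyr::bind_rows(
    layer_row("input", "input", sprintf("(None, %d, 1)", L)),
    layer_row("permute", "permute", sprintf("(None, 1, %d)", L), "input"),
    layer_row("conv1d_1", "conv1d", "(None, 1, 128)", "permute",
              filters = 128L, kernel = 8L, in_channels = L),
    layer_row("bn_1", "batchnorm", "(None, 1, 128)", "conv1d_1", channels = 128L),
    layer_row("relu_1", "relu", "(None, 1, 128)", "bn_1"),
    layer_row("conv1d_2", "conv1d", "(None, 1, 256)", "relu_1",
              filters = 256L, kernel = 5L, in_channels = 128L),
    layer_row("bn_2", "batchnorm", "(None, 1, 256)", "conv1d_2", channels = 256L),
    layer_row("relu_2", "relu", "(None, 1, 256)", "bn_2"),
    layer_row("conv1d_3", "conv1d", "(None, 1, 128)", "relu_2",
              filters = 128L, kernel = 3L, in_channels = 256L),
    layer_row("bn_3", "batchnorm", "(None, 1, 128)", "conv1d_3", channels = 128L),
    layer_row("lstm", "lstm", sprintf("(None, %d)", lstm_units), "input",
              units = lstm_units, input_dim = 1L),
    layer_row("relu_3", "relu", "(None, 1, 128)", "bn_3"),
    layer_row("dropout", "dropout", sprintf("(None, %d)", lstm_units), "lstm",
              rate = dropout),
    layer_row("gap", "global_avg_pool", "(None, 128)", "relu_3"),
    layer_row("concat", "concat", sprintf("(None, %d)", lstm_units + 128L),
              "dropout, gap"),
    layer_row("dense", "dense", sprintf("(None, %d)", n_classes),
              "concat", units = n_classes, in_dim = lstm_units + 128L,
              activation = "softmax"))
  new_arch_spec("lstm_fcn", input_length, n_classes, layers)
}

#' Total parameter count of an architecture
#'
#' Closed-form count, independent of any instantiated weights; per-layer
#' counts are available through [tidy.arch_spec()].
#'
#' @param spec An `arch_spec`.
#' @return Total parameter count (a single number).
#' @export
parameter_count <- function(spec) {
  if (!inherits(spec, "arch_spec")) {
    stop_ecg("`spec` must be an arch_spec.", class = "ecgbeat_validation_error")
  }
  sum(spec$layers$param_count)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec %s: input length %d, %d classes, %s parameters>\n",
              x$name, x$input_length, x$n_classes,
              format(parameter_count(x), big.mark = ",")))
  print(dplyr::select(x$layers, "layer", "kind", "output", "param_count"))
  invisible(x)
}

#' Tidy an architecture specification
#'
#' @param x An `arch_spec`.
#' @param ... Unused.
#' @return A tibble with one row per layer: `layer`, `kind`, `output`,
#'   `input` (connectivity) and `param_count`.
#' @export
tidy.arch_spec <- function(x, ...) {
  dplyr::select(x$layers, "layer", "kind", "output", "input", "param_count")
}

#' Training configuration
#'
#' Defaults follow the full-scale training protocol: Adam with learning rate
#' 0.001, categorical cross-entropy, batch size 256, up to 50 epochs, a
#' stratified 70/30 train/test split, and dropout 0.2 on the dense path of
#' the sequential architectures.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param train_fraction Fraction of beats in the training split.
#' @param dropout Dropout rate applied after the hidden dense layer of the
#'   sequential architectures (the LSTM-FCN recurrent branch keeps its own
#'   0.8 rate from the spec).
#' @param seed Integer seed controlling the split, initial weights, shuffling
#'   and dropout masks.
#' @param early_stopping_patience Stop when the training loss has not
#'   improved for this many epochs; `Inf` (default) disables it.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 256L,
                         learning_rate = 0.001, train_fraction = 0.7,
                         dropout = 0.2, seed = 1L,
                         early_stopping_patience = Inf) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_ecg("`train_fraction` must be in (0, 1).",
             class = "ecgbeat_validation_error")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 train_fraction = train_fraction, dropout = dropout,
                 seed = as.integer(seed),
                 early_stopping_patience = early_stopping_patience),
            class = "train_config")
}
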