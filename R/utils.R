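#' @importFrom rlang abort warn .data
#' @importFrom stats median sd rnorm runif fft predict
#' @importFrom tibble tibble as_tibble
NULL

# Classed validation error shared by all modules.
stop_ecg <- function(msg, class = "ecgbeat_error", ...) {
  abort(msg, class = c(class, "ecgbeat_error"), ...)
}

check_numeric_signal <- function(x, arg = "signal") {
  if (!is.numeric(x) || length(x) == 0) {
    stop_ecg(sprintf("`%s` must be a non-empty numeric vector.", arg),
             class = "ecgbeat_validation_error")
  }
  if (!all(is.finite(x))) {
    stop_ecg(sprintf("`%s` contains non-finite samples.", arg),
             class = "ecgbeat_validation_error")
  }
  invisible(x)
}

check_scalar <- function(x, arg, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (positive && x <= 0)) {
    stop_ecg(sprintf("`%s` must be a single %s number.", arg,
                     if (positive) "positive finite" else "finite"),
             class = "ecgbeat_validation_error")
  }
  invisible(x)
}

#' AAMI heartbeat class labels
#'
#' The five-category beat taxonomy of the Association for the Advancement of
#' Medical Instrumentation: N (normal), S (supraventricular ectopic),
#' V (ventricular ectopic), F (fusion), Q (unknown).
#'
#' @return Character vector of the five class labels, in canonical order.
#' @export
aami_classes <- function() c("N", "S", "V", "F", "Q")

as_aami_factor <- function(x) {
  factor(as.character(x), levels = aami_classes())
}
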