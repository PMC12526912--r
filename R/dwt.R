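# Discrete wavelet transform with zero extension.
#
# Analysis: full convolution of the signal with the decomposition filter,
# keeping every second sample; a level-1 band of an n-sample signal with a
# length-f filter therefore holds floor((n + f - 1) / 2) coefficients, which
# is every coefficient whose filter support overlaps the signal.  Because the
# even translates of an orthonormal filter pair form an orthonormal basis of
# the zero-extended sequence space, the transform conserves energy exactly
# and the adjoint (upsample, convolve with the time-reversed filters, trim
# f - 2 leading samples) inverts it exactly.

#' Orthonormal wavelet filter banks
#'
#' Decomposition and reconstruction filters for the Daubechies family members
#' used in this package. `dec_hi` follows the quadrature-mirror convention
#' `dec_hi[k] = (-1)^k dec_lo[f - 1 - k]` (0-based), and the reconstruction
#' filters are the time-reversed decomposition filters.
#'
#' @param wavelet One of `"haar"`, `"db4"`, `"db8"`.
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and the filter
#'   `length`.
#' @export
wavelet_filters <- function(wavelet = "db8") {
  dec_lo <- switch(
    wavelet,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    db8 = c(-0.00011747678412476953, 0.0006754494064505693,
            -0.00039174037337694705, -0.004870352993451574,
            0.008746094047405777, 0.013981027917398282,
            -0.044088253930794755, -0.017369301001807547,
            0.12874742662047847, 0.0004724845739132828,
            -0.2840155429615469, -0.015829105256349306,
            0.5853546836542067, 0.6756307362972898,
            0.31287159091429995, 0.05441584224310401),
    stop_ecg(sprintf("Unknown wavelet '%s'. Available: haar, db4, db8.", wavelet),
             class = "ecgbeat_validation_error")
  )
  f <- length(dec_lo)
  dec_hi <- (-1)^(seq_len(f) - 1) * rev(dec_lo)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi),
       length = f, wavelet = wavelet)
}

# Full ("open") linear convolution of x with filter h.
conv_full <- function(x, h) {
  nx <- length(x); nh <- length(h)
  if (nx + nh < 64) {
    # direct form avoids FFT round-off on tiny inputs
    out <- numeric(nx + nh - 1)
    for (j in seq_len(nh)) out[j:(j + nx - 1)] <- out[j:(j + nx - 1)] + h[j] * x
    return(out)
  }
  n <- nx + nh - 1L
  m <- stats::nextn(n, 2)
  Re(fft(fft(c(x, numeric(m - nx))) * fft(c(h, numeric(m - nh))),
         inverse = TRUE))[seq_len(n)] / m
}

#' Maximum feasible decomposition depth
#'
#' The depth at which the coarsest approximation band is still longer than the
#' filter: `floor(log2(n / (f - 1)))`.
#'
#' @param n Signal length.
#' @param wavelet Wavelet name (see [wavelet_filters()]).
#' @return Integer depth (possibly 0 for very short signals).
#' @export
dwt_max_level <- function(n, wavelet = "db8") {
  f <- wavelet_filters(wavelet)$length
  if (n < f) return(0L)
  as.integer(floor(log2(n / (f - 1))))
}

dwt_single <- function(x, filt) {
  a_full <- conv_full(x, filt$dec_lo)
  d_full <- conv_full(x, filt$dec_hi)
  keep <- seq(2L, length(a_full), by = 2L)
  list(a = a_full[keep], d = d_full[keep])
}

idwt_single <- function(a, d, filt, n_out) {
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq(1L, length(u), by = 2L)] <- c
    u
  }
  rec <- conv_full(up(a), filt$rec_lo) + conv_full(up(d), filt$rec_hi)
  rec[(filt$length - 1L):(filt$length - 2L + n_out)]
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a signal into approximation coefficients at the deepest level
#' and detail coefficients at every level, by recursive filtering and
#' downsampling with zero extension. Only the deepest approximation band
#' `A_L` is used as the wavelet feature vector; the details carry the
#' high-frequency content that soft thresholding removes during denoising.
#'
#' @param x Numeric signal.
#' @param wavelet Wavelet name (default `"db8"`).
#' @param level Decomposition depth `L`; must not exceed
#'   [dwt_max_level()] for the signal length.
#' @return An object of class `ecg_dwt`: list with `a` (approximation at level
#'   `L`), `d` (list of detail vectors, level L down to 1), `lengths` (input
#'   length at each level, needed for exact inversion), `wavelet`, `level`.
#' @seealso [dwt_reconstruct()]
#' @export
dwt_decompose <- function(x, wavelet = "db8", level = 1L) {
  check_numeric_signal(x)
  check_scalar(level, "level")
  filt <- wavelet_filters(wavelet)
  maxlev <- dwt_max_level(length(x), wavelet)
  if (level > maxlev) {
    stop_ecg(sprintf("level %d infeasible for signal of length %d (max %d).",
                     level, length(x), maxlev),
             class = "ecgbeat_validation_error")
  }
  d <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lengths[j] <- length(a)
    dec <- dwt_single(a, filt)
    a <- dec$a
    d[[level - j + 1L]] <- dec$d
  }
  structure(list(a = a, d = d, lengths = lengths, wavelet = wavelet,
                 level = as.integer(level)),
            class = "ecg_dwt")
}

#' Inverse multilevel discrete wavelet transform
#'
#' Exact inverse of [dwt_decompose()]: reconstructs the signal from the
#' deepest approximation band and all detail bands. Zeroing the detail
#' vectors before reconstruction yields the low-pass "dominant pattern"
#' version of the signal.
#'
#' @param coeffs An `ecg_dwt` object.
#' @return Numeric vector of the original signal length.
#' @export
dwt_reconstruct <- function(coeffs) {
  if (!inherits(coeffs, "ecg_dwt")) {
    stop_ecg("`coeffs` must come from dwt_decompose().",
             class = "ecgbeat_validation_error")
  }
  filt <- wavelet_filters(coeffs$wavelet)
  a <- coeffs$a
  for (j in seq_len(coeffs$level)) {
    d <- coeffs$d[[j]]
    if (length(d) != length(a)) {
      stop_ecg("Inconsistent coefficient lengths in `coeffs`.",
               class = "ecgbeat_validation_error")
    }
    a <- idwt_single(a, d, filt, coeffs$lengths[coeffs$level - j + 1L])
  }
  a
}
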