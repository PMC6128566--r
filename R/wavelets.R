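#' Wavelet filters
#'
#' Construct a wavelet filter object for the 2-D discrete wavelet transform.
#' Two kinds are supported: orthonormal FIR filter banks (`"haar"`, `"d4"`,
#' `"sym4"`) and the Shannon wavelet (`"shannon"`), an ideal half-band split
#' applied exactly in the Fourier domain. The Shannon wavelet is exact for the
#' periodic, power-of-two frames used throughout this package and is the
#' default for feature extraction.
#'
#' For FIR filters the low-pass taps `a` satisfy `sum(a) == sqrt(2)` and the
#' high-pass taps are the quadrature mirror `b[m] = (-1)^m a[L-1-m]`, so the
#' analysis is orthonormal (energy preserving).
#'
#' @param name one of `"shannon"`, `"haar"`, `"d4"` (4-tap Daubechies),
#'   `"sym4"` (8-tap symlet).
#' @return An object of class `wavelet_filter` with fields `name`, `mode`
#'   (`"fir"` or `"fourier"`), and for FIR filters `lowpass`, `highpass`.
#' @examples
#' wavelet_filter("haar")
#' wavelet_filter("shannon")
#' @export
wavelet_filter <- function(name = c("shannon", "haar", "d4", "sym4")) {
  name <- match.arg(name)
  if (name == "shannon") {
    out <- list(name = "shannon", mode = "fourier",
                lowpass = NULL, highpass = NULL)
    class(out) <- "wavelet_filter"
    return(out)
  }
  lowpass <- switch(name,
    haar = rep(1 / sqrt(2), 2),
    # (1+sqrt(3), 3+sqrt(3), 3-sqrt(3), 1-sqrt(3)) / (4*sqrt(2))
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    sym4 = c(0.0322231006040427, -0.012603967262037833,
             -0.09921954357684722, 0.29785779560527736,
             0.8037387518059161, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333))
  L <- length(lowpass)
  highpass <- (-1)^(seq_len(L) - 1) * rev(lowpass)
  out <- list(name = name, mode = "fir",
              lowpass = lowpass, highpass = highpass)
  class(out) <- "wavelet_filter"
  out
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat("Wavelet filter:", x$name, sprintf("(%s mode)\n", x$mode))
  if (x$mode == "fir") {
    cat("  lowpass: ", paste(signif(x$lowpass, 6), collapse = " "), "\n")
    cat("  highpass:", paste(signif(x$highpass, 6), collapse = " "), "\n")
  }
  invisible(x)
}

.as_filter <- function(filter) {
  if (inherits(filter, "wavelet_filter")) return(filter)
  wavelet_filter(filter)
}

# One analysis step along the columns of x (length-N signals, N even):
# out[n, ] = g * sum_m h[m] x[(2(n-1) + m - 1 + offset) mod N + 1, ]
# i.e. correlation with stride-2 downsampling and periodic extension.
# The literal (printed-form) convention uses gain 2 and offset -2.
.fir_analysis_cols <- function(x, h, offset = 0L, gain = 1) {
  N <- nrow(x); N2 <- N %/% 2L
  out <- matrix(0, N2, ncol(x))
  base <- 2L * (seq_len(N2) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L) + offset) %% N + 1L
    out <- out + h[m] * x[idx, , drop = FALSE]
  }
  gain * out
}

# Adjoint of .fir_analysis_cols (the inverse for an orthonormal bank).
.fir_synthesis_cols <- function(low, high, h, g, offset = 0L, gain = 1) {
  N2 <- nrow(low); N <- 2L * N2
  x <- matrix(0, N, ncol(low))
  base <- 2L * (seq_len(N2) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L) + offset) %% N + 1L
    x[idx, ] <- x[idx, ] + h[m] * low
  }
  for (m in seq_along(g)) {
    idx <- (base + (m - 1L) + offset) %% N + 1L
    x[idx, ] <- x[idx, ] + g[m] * high
  }
  x / gain
}

# Ideal half-band (Shannon) split along columns, exact in the Fourier domain.
# Orthonormal: the boundary bins k = N/4 and 3N/4 are shared between the two
# sub-bands as their real and imaginary parts, so energy is conserved exactly
# and the split is invertible.
.shannon_split_cols <- function(x) {
  N <- nrow(x)
  if (N %% 4L != 0L)
    stop("fourier-mode split requires a signal length divisible by 4")
  N2 <- N %/% 2L; N4 <- N %/% 4L
  X <- stats::mvfft(x)
  Lh <- matrix(0 + 0i, N2, ncol(x))
  Hh <- matrix(0 + 0i, N2, ncol(x))
  s2 <- sqrt(2)
  Lh[seq_len(N4), ] <- X[seq_len(N4), , drop = FALSE] / s2          # k' = 0..N4-1
  Lh[N4 + 1L, ] <- (X[N4 + 1L, , drop = FALSE] +
                    X[3L * N4 + 1L, , drop = FALSE]) / 2            # boundary (real part)
  if (N4 + 2L <= N2)
    Lh[(N4 + 2L):N2, ] <- X[(N2 + N4 + 2L):N, , drop = FALSE] / s2  # negative low freqs
  Hh[1L, ] <- -0.5i * (X[N4 + 1L, , drop = FALSE] -
                       X[3L * N4 + 1L, , drop = FALSE])             # boundary (imag part)
  Hh[2L:N2, ] <- X[(N4 + 2L):(N4 + N2), , drop = FALSE] / s2
  low <- Re(stats::mvfft(Lh, inverse = TRUE)) / N2
  high <- Re(stats::mvfft(Hh, inverse = TRUE)) / N2
  list(low = low, high = high)
}

.shannon_merge_cols <- function(low, high) {
  N2 <- nrow(low); N <- 2L * N2; N4 <- N %/% 4L
  Lh <- stats::mvfft(low)
  Hh <- stats::mvfft(high)
  X <- matrix(0 + 0i, N, ncol(low))
  s2 <- sqrt(2)
  X[seq_len(N4), ] <- s2 * Lh[seq_len(N4), , drop = FALSE]
  if (N4 + 2L <= N2)
    X[(N2 + N4 + 2L):N, ] <- s2 * Lh[(N4 + 2L):N2, , drop = FALSE]
  X[(N4 + 2L):(N4 + N2), ] <- s2 * Hh[2L:N2, , drop = FALSE]
  X[N4 + 1L, ] <- Lh[1L * (N4 + 1L), , drop = FALSE] + 1i * Hh[1L, , drop = FALSE]
  X[3L * N4 + 1L, ] <- Lh[N4 + 1L, , drop = FALSE] - 1i * Hh[1L, , drop = FALSE]
  Re(stats::mvfft(X, inverse = TRUE)) / N
}

.split_cols <- function(x, filter, literal = FALSE) {
  if (filter$mode == "fourier") {
    .shannon_split_cols(x)
  } else {
    offset <- if (literal) -2L else 0L
    gain <- if (literal) 2 else 1
    list(low = .fir_analysis_cols(x, filter$lowpass, offset, gain),
         high = .fir_analysis_cols(x, filter$highpass, offset, gain))
  }
}

#' One level of the 2-D discrete wavelet transform
#'
#' Applies the analysis filter bank separably — first along columns (the
#' vertical direction), then along rows — with periodic boundary extension and
#' stride-2 downsampling, yielding the four half-size frequency sub-bands.
#' Band naming: the first letter is the vertical filter, the second the
#' horizontal one, so `LH` holds horizontal detail, `HL` vertical detail and
#' `HH` diagonal detail.
#'
#' By default the orthonormal convention is used (normalisation carried by the
#' filter taps). `literal_normalisation = TRUE` instead applies the textbook
#' forward-transform form with an explicit leading factor 2 and an index shift
#' of two samples; all sub-band statistics are scale-covariant, so feature
#' ranking is unaffected by the choice.
#'
#' @param x numeric matrix with both dimensions even (and divisible by 4 for
#'   the Fourier-mode Shannon filter).
#' @param filter a [wavelet_filter()] object or filter name.
#' @param literal_normalisation logical; apply the factor-2 convention
#'   (FIR filters only).
#' @return A list of class `subband_set` with elements `LL`, `LH`, `HL`, `HH`,
#'   each of dimension `dim(x)/2`.
#' @seealso [dwt_multilevel()], [idwt2()]
#' @export
dwt2 <- function(x, filter = wavelet_filter("shannon"),
                 literal_normalisation = FALSE) {
  filter <- .as_filter(filter)
  x <- as.matrix(x)
  if (any(dim(x) %% 2L != 0L) || any(dim(x) < 2L))
    stop("dwt2 requires even dimensions of at least 2")
  v <- .split_cols(x, filter, literal_normalisation)            # vertical pass
  hL <- .split_cols(t(v$low), filter, literal_normalisation)    # horizontal pass
  hH <- .split_cols(t(v$high), filter, literal_normalisation)
  out <- list(LL = t(hL$low), LH = t(hL$high),
              HL = t(hH$low), HH = t(hH$high))
  class(out) <- "subband_set"
  out
}

#' Invert one level of the 2-D discrete wavelet transform
#'
#' Exact inverse of [dwt2()] for orthonormal FIR filters and for the
#' Fourier-mode Shannon filter.
#'
#' @param bands a `subband_set` as returned by [dwt2()].
#' @inheritParams dwt2
#' @return The reconstructed matrix.
#' @export
idwt2 <- function(bands, filter = wavelet_filter("shannon"),
                  literal_normalisation = FALSE) {
  filter <- .as_filter(filter)
  merge_cols <- function(low, high) {
    if (filter$mode == "fourier") {
      .shannon_merge_cols(low, high)
    } else {
      offset <- if (literal_normalisation) -2L else 0L
      gain <- if (literal_normalisation) 2 else 1
      .fir_synthesis_cols(low, high, filter$lowpass, filter$highpass,
                          offset, gain)
    }
  }
  vlow <- t(merge_cols(t(bands$LL), t(bands$LH)))
  vhigh <- t(merge_cols(t(bands$HL), t(bands$HH)))
  merge_cols(vlow, vhigh)
}

#' Multi-level 2-D wavelet decomposition
#'
#' Recursively decomposes the `LL` (coarse) band: level `j + 1` is computed
#' from level `j`'s `LL`, the standard Mallat pyramid. For a 512x512 input and
#' six levels the final bands are 8x8.
#'
#' @param x numeric matrix; each dimension must be divisible by `2^levels`.
#' @param levels number of decomposition levels.
#' @inheritParams dwt2
#' @return A list of `levels` `subband_set`s (level 1 first).
#' @export
dwt_multilevel <- function(x, filter = wavelet_filter("shannon"), levels = 6L,
                           literal_normalisation = FALSE) {
  x <- as.matrix(x)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (any(dim(x) %% (2L^levels) != 0L))
    stop(sprintf("dimensions %dx%d not divisible by 2^%d",
                 nrow(x), ncol(x), levels))
  filter <- .as_filter(filter)
  out <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    bands <- dwt2(cur, filter, literal_normalisation)
    out[[j]] <- bands
    cur <- bands$LL
  }
  out
}

#' Reconstruct from a multi-level decomposition
#'
#' @param pyramid list of `subband_set`s from [dwt_multilevel()].
#' @inheritParams dwt2
#' @return The reconstructed matrix.
#' @export
idwt_multilevel <- function(pyramid, filter = wavelet_filter("shannon"),
                            literal_normalisation = FALSE) {
  filter <- .as_filter(filter)
  cur <- NULL
  for (j in rev(seq_along(pyramid))) {
    bands <- pyramid[[j]]
    if (!is.null(cur)) bands$LL <- cur
    cur <- idwt2(bands, filter, literal_normalisation)
  }
  cur
}
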