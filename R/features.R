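.stat_names <- c("mean", "abs_mean", "energy", "variance",
                 "mean_row_skew", "var_row_skew",
                 "mean_col_skew", "var_col_skew",
                 "mean_row_kurt", "var_row_kurt",
                 "mean_col_kurt", "var_col_kurt")
.band_names <- c("LL", "LH", "HL", "HH")
.channel_names <- c("R", "G", "B", "Luma")

# Population skewness / raw kurtosis per row; rows whose central second
# moment is (numerically) zero contribute 0 for both, so constant regions
# such as blank padding yield finite features.
.row_moments <- function(x) {
  m <- rowMeans(x)
  xc <- x - m
  m2 <- rowMeans(xc^2)
  m3 <- rowMeans(xc^3)
  m4 <- rowMeans(xc^4)
  ok <- m2 > 1e-24
  skew <- ifelse(ok, m3 / m2^1.5, 0)
  kurt <- ifelse(ok, m4 / m2^2, 0)
  list(skew = skew, kurt = kurt)
}

.pop_var <- function(v) mean((v - mean(v))^2)

#' Sub-band summary statistics
#'
#' The twelve statistics computed from every wavelet sub-band: four global
#' measures — the mean, the absolute mean, the energy (mean of squared
#' coefficients) and the (population) variance — plus the mean and variance of
#' the per-row and per-column skewness and kurtosis. Skewness is `m3/m2^(3/2)`
#' and kurtosis is raw (not excess) `m4/m2^2`, both with population moment
#' estimators; rows or columns with zero variance contribute 0.
#'
#' @param band numeric matrix, at least 2x2.
#' @return Named numeric vector of length 12 in the canonical order
#'   `mean, abs_mean, energy, variance, mean_row_skew, var_row_skew,
#'   mean_col_skew, var_col_skew, mean_row_kurt, var_row_kurt,
#'   mean_col_kurt, var_col_kurt`.
#' @examples
#' subband_statistics(matrix(c(1, -1, -1, 1), 2, 2))
#' @export
subband_statistics <- function(band) {
  band <- as.matrix(band)
  if (length(band) == 0L) stop("empty band")
  if (any(dim(band) < 2L)) stop("band must be at least 2x2")
  v <- as.vector(band)
  rw <- .row_moments(band)
  cl <- .row_moments(t(band))
  out <- c(mean(v), mean(abs(v)), mean(v^2), .pop_var(v),
           mean(rw$skew), .pop_var(rw$skew),
           mean(cl$skew), .pop_var(cl$skew),
           mean(rw$kurt), .pop_var(rw$kurt),
           mean(cl$kurt), .pop_var(cl$kurt))
  names(out) <- .stat_names
  out
}

#' Canonical feature schema
#'
#' Index table for the wavelet feature bank: features are ordered by
#' decomposition level (outermost), then sub-band (`LL`, `LH`, `HL`, `HH`),
#' then channel (`R`, `G`, `B`, `Luma`), then statistic (innermost). With the
#' default six levels this yields 6 x 4 x 4 x 12 = 1152 features.
#'
#' @param levels number of decomposition levels.
#' @return A data.frame with columns `index`, `level`, `band`, `channel`,
#'   `statistic`, `name`; names follow `L{level}_{band}_{channel}_{stat}`.
#' @export
feature_schema <- function(levels = 6L) {
  g <- expand.grid(statistic = .stat_names, channel = .channel_names,
                   band = .band_names, level = seq_len(levels),
                   stringsAsFactors = FALSE)
  g <- g[, c("level", "band", "channel", "statistic")]
  g$index <- seq_len(nrow(g))
  g$name <- sprintf("L%d_%s_%s_%s", g$level, g$band, g$channel, g$statistic)
  g[, c("index", "level", "band", "channel", "statistic", "name")]
}

#' Luminance channel
#'
#' Rec.601 luma: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image H x W x 3 array.
#' @return H x W matrix.
#' @export
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Extract the wavelet sub-band statistics feature vector
#'
#' Runs a multi-level 2-D wavelet decomposition of each of the R, G, B and
#' luminance channels of a canonical 512x512 frame and computes the twelve
#' [subband_statistics()] from every sub-band at every level, producing the
#' 1152-dimensional feature vector (6 levels x 4 sub-bands x 4 channels x 12
#' statistics) in the canonical [feature_schema()] order.
#'
#' @param image H x W x 3 array in `[0, 1]` with both dimensions divisible by
#'   `2^levels` (the canonical frame is 512x512).
#' @param filter a [wavelet_filter()] or name; default the Shannon wavelet.
#' @param levels decomposition depth, default 6.
#' @param literal_normalisation see [dwt2()].
#' @return Named numeric vector of length `levels * 4 * 4 * 12`.
#' @export
extract_features <- function(image, filter = wavelet_filter("shannon"),
                             levels = 6L, literal_normalisation = FALSE) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  filter <- .as_filter(filter)
  levels <- as.integer(levels)
  channels <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3],
                   Luma = luminance(image))
  pyramids <- lapply(channels, dwt_multilevel, filter = filter,
                     levels = levels,
                     literal_normalisation = literal_normalisation)
  schema <- feature_schema(levels)
  out <- numeric(nrow(schema))
  i <- 1L
  for (lev in seq_len(levels)) {
    for (band in .band_names) {
      for (ch in .channel_names) {
        out[i:(i + 11L)] <- subband_statistics(pyramids[[ch]][[lev]][[band]])
        i <- i + 12L
      }
    }
  }
  names(out) <- schema$name
  out
}
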