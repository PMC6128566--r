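# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results from first principles (direct
# convolution, explicit moment sums, dense eigendecompositions) so they share
# no code path with the package implementation they check.

# direct correlation + stride-2 downsampling with periodic extension,
# computed pixel by pixel
oracle_fir_cols <- function(x, h) {
  N <- nrow(x); N2 <- N %/% 2
  out <- matrix(0, N2, ncol(x))
  for (j in seq_len(ncol(x))) {
    for (n in seq_len(N2)) {
      acc <- 0
      for (m in seq_along(h)) {
        idx <- (2 * (n - 1) + (m - 1)) %% N + 1
        acc <- acc + h[m] * x[idx, j]
      }
      out[n, j] <- acc
    }
  }
  out
}

oracle_dwt2 <- function(x, lowpass, highpass) {
  vl <- oracle_fir_cols(x, lowpass)
  vh <- oracle_fir_cols(x, highpass)
  list(LL = t(oracle_fir_cols(t(vl), lowpass)),
       LH = t(oracle_fir_cols(t(vl), highpass)),
       HL = t(oracle_fir_cols(t(vh), lowpass)),
       HH = t(oracle_fir_cols(t(vh), highpass)))
}

# explicit population-moment statistics of a band, summed cell by cell
oracle_band_stats <- function(b) {
  v <- as.vector(b)
  n <- length(v)
  mu <- sum(v) / n
  axis_stats <- function(rows) {
    sk <- ku <- numeric(length(rows))
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      m <- sum(r) / length(r)
      m2 <- sum((r - m)^2) / length(r)
      m3 <- sum((r - m)^3) / length(r)
      m4 <- sum((r - m)^4) / length(r)
      if (m2 > 1e-24) { sk[i] <- m3 / m2^1.5; ku[i] <- m4 / m2^2 }
    }
    pv <- function(z) sum((z - sum(z) / length(z))^2) / length(z)
    c(mean(sk), pv(sk), mean(ku), pv(ku))
  }
  rw <- axis_stats(split(b, row(b)))
  cl <- axis_stats(split(b, col(b)))
  c(mean = mu, abs_mean = sum(abs(v)) / n, energy = sum(v^2) / n,
    variance = sum((v - mu)^2) / n,
    mean_row_skew = rw[1], var_row_skew = rw[2],
    mean_col_skew = cl[1], var_col_skew = cl[2],
    mean_row_kurt = rw[3], var_row_kurt = rw[4],
    mean_col_kurt = cl[3], var_col_kurt = cl[4])
}

# exhaustive ReliefF rollout with explicit loops (two classes)
oracle_relieff <- function(X, y, k) {
  p <- nrow(X); q <- ncol(X)
  rng <- apply(X, 2, max) - apply(X, 2, min)
  Xn <- X
  for (f in seq_len(q))
    Xn[, f] <- if (rng[f] > 0) (X[, f] - min(X[, f])) / rng[f] else 0
  w <- numeric(q)
  for (i in seq_len(p)) {
    d <- rowSums(abs(Xn - matrix(Xn[i, ], p, q, byrow = TRUE)))
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    hits <- same[order(d[same])][seq_len(k)]
    misses <- other[order(d[other])][seq_len(k)]
    for (f in seq_len(q)) {
      if (rng[f] == 0) next
      w[f] <- w[f] - sum(abs(Xn[hits, f] - Xn[i, f])) / (k * p) +
        sum(abs(Xn[misses, f] - Xn[i, f])) / (k * p)
    }
  }
  w
}

# two-level disk image fixture with its ground-truth mask
make_disk_image <- function(side, radius, centre = c(side / 2, side / 2),
                            fg = 0.2, bg = 0.8) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)
  ys <- t(xs)
  disk <- (xs - centre[1])^2 + (ys - centre[2])^2 <= radius^2
  img <- array(bg, c(side, side, 3))
  for (k in 1:3) {
    ch <- img[, , k]; ch[disk] <- fg; img[, , k] <- ch
  }
  list(image = img, mask = disk)
}
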