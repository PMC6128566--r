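# run expr with a private RNG state so generators are deterministic under
# `seed` without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.value_noise <- function(side, lattice, amp) {
  g <- matrix(stats::rnorm(lattice * lattice), lattice, lattice)
  if (lattice == side) return(amp * g)
  up <- EBImage::resize(EBImage::Image(g), w = side, h = side,
                        filter = "bilinear")
  amp * as.array(up)
}

#' Simulate a synthetic dermoscopic lesion image
#'
#' Generates a skin-toned canvas with a darker, textured, elliptical lesion
#' whose border is perturbed sinusoidally — emulating the global asymmetry,
#' multi-scale texture and irregular borders of real lesions — together with
#' the ground-truth mask. The excise-class defaults have strictly larger
#' fine-scale (high-octave) texture amplitude and border irregularity than
#' the benign defaults, so the two classes differ in exactly the properties
#' the wavelet feature bank measures. Fully deterministic for a given seed.
#'
#' This simulation captures two-region contrast, border geometry and texture
#' spectra; it does not attempt photorealism (no hair, ruler marks, specular
#' reflection or colour variegation).
#'
#' @param seed RNG seed.
#' @param class `"excise"` or `"benign"`; selects the default texture and
#'   border parameters.
#' @param side canvas side in pixels (default 512).
#' @param axes ellipse semi-axes in pixels (default `c(0.30, 0.22) * side`).
#' @param orientation ellipse orientation in radians; default drawn from the
#'   seeded generator.
#' @param base_contrast scales the lesion darkening relative to skin (1 =
#'   full default contrast).
#' @param texture_amp amplitudes of the four texture octaves, coarse to
#'   per-pixel; class defaults if `NULL`.
#' @param border_irregularity relative amplitude of the sinusoidal border
#'   perturbation; class default if `NULL`.
#' @return List with `image` (side x side x 3 array in `[0, 1]`), `mask`
#'   (ground-truth logical matrix) and `spec` (the realised parameters).
#' @export
simulate_lesion_image <- function(seed = 1L,
                                  class = c("excise", "benign"),
                                  side = 512L, axes = NULL,
                                  orientation = NULL, base_contrast = 1,
                                  texture_amp = NULL,
                                  border_irregularity = NULL) {
  class <- match.arg(class)
  side <- as.integer(side)
  if (is.null(axes)) axes <- c(0.30, 0.22) * side
  if (any(axes > side / 2)) stop("invalid spec: ellipse exceeds the canvas")
  if (is.null(texture_amp))
    texture_amp <- if (class == "excise") c(0.05, 0.03, 0.03, 0.020)
                   else c(0.05, 0.03, 0.012, 0.004)
  if (is.null(border_irregularity))
    border_irregularity <- if (class == "excise") 0.18 else 0.04
  skin <- c(0.80, 0.60, 0.52)      # plausible dermoscopy skin tone
  lesion <- c(0.42, 0.30, 0.26)    # pigmented lesion tone
  .with_seed(seed, {
    if (is.null(orientation)) orientation <- stats::runif(1, 0, pi)
    cx <- side / 2 + 0.5; cy <- side / 2 + 0.5
    xs <- matrix(rep(seq_len(side), each = side), side, side) - cx
    ys <- matrix(rep(seq_len(side), times = side), side, side) - cy
    xr <- cos(orientation) * xs + sin(orientation) * ys
    yr <- -sin(orientation) * xs + cos(orientation) * ys
    theta <- atan2(yr / axes[2], xr / axes[1])
    # sinusoidal border perturbation, harmonics 3..6, normalised to max 1
    h <- 3:6
    ch <- stats::rnorm(length(h)); dh <- stats::rnorm(length(h))
    s <- matrix(0, side, side)
    for (i in seq_along(h))
      s <- s + ch[i] * cos(h[i] * theta) + dh[i] * sin(h[i] * theta)
    mx <- max(abs(s))
    if (mx > 0) s <- s / mx
    rr <- sqrt((xr / axes[1])^2 + (yr / axes[2])^2)
    mask <- rr <= 1 + border_irregularity * s
    lattices <- pmax(2L, as.integer(side / c(64L, 16L, 4L, 1L)))
    tex <- matrix(0, side, side)
    for (o in seq_along(texture_amp))
      tex <- tex + .value_noise(side, lattices[o], texture_amp[o])
    img <- array(0, c(side, side, 3L))
    for (k in 1:3) {
      ch_img <- matrix(skin[k], side, side)
      ch_img[mask] <- skin[k] - base_contrast * (skin[k] - lesion[k]) +
        tex[mask]
      img[, , k] <- ch_img
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img, mask = mask,
         spec = list(seed = seed, class = class, side = side, axes = axes,
                     orientation = orientation, base_contrast = base_contrast,
                     texture_amp = texture_amp,
                     border_irregularity = border_irregularity))
  })
}

#' Simulate a synthetic feature table
#'
#' Generates a two-class feature table with the structure of the wavelet
#' feature bank: features fall into correlated blocks (emulating the linear
#' relationships between decomposition levels and between statistics of the
#' same band) via a shared-factor model with within-block correlation `rho`;
#' the excise class is shifted by `delta` standard deviations on
#' `n_informative` randomly placed informative features. Marginal scales are
#' standardised. The default class sizes are the study scale, 165 excise and
#' 85 no-excise rows, so cross-validation behaviour under that imbalance is
#' exercised.
#'
#' @param seed RNG seed.
#' @param n_pos,n_neg excise / no-excise row counts (defaults 165 / 85).
#' @param q number of features (default 1152).
#' @param n_informative number of class-informative features (default 20).
#' @param delta standardised mean shift on informative features (default 2).
#' @param block_size correlated-block size (default 12).
#' @param rho within-block correlation (default 0.5).
#' @return List with `X` (`(n_pos + n_neg) x q` matrix, excise rows first),
#'   `y` (1 = excise), `informative` (ground-truth informative indices).
#' @export
simulate_feature_table <- function(seed = 1L, n_pos = 165L, n_neg = 85L,
                                   q = 1152L, n_informative = 20L,
                                   delta = 2, block_size = 12L, rho = 0.5) {
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  q <- as.integer(q)
  if (n_pos < 1L || n_neg < 1L) stop("invalid spec: non-positive class size")
  if (n_informative > q) stop("invalid spec: n_informative > q")
  stopifnot(rho >= 0, rho < 1)
  n <- n_pos + n_neg
  .with_seed(seed, {
    blocks <- rep(seq_len(ceiling(q / block_size)), each = block_size)[1:q]
    nb <- max(blocks)
    Z <- matrix(stats::rnorm(n * nb), n, nb)
    E <- matrix(stats::rnorm(n * q), n, q)
    X <- sqrt(rho) * Z[, blocks, drop = FALSE] + sqrt(1 - rho) * E
    informative <- sort(sample.int(q, n_informative))
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    X[y == 1L, informative] <- X[y == 1L, informative] + delta
    colnames(X) <- if (q == 1152L) feature_schema(6L)$name
                   else sprintf("V%d", seq_len(q))
    list(X = X, y = y, informative = informative)
  })
}
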