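.check_rgb <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 array")
  if (!all(is.finite(image)) || min(image) < 0 || max(image) > 1)
    stop("pixel values must be finite and in [0, 1]")
  invisible(image)
}

.to_ebimage <- function(image) {
  EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
}

.from_ebimage <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  out <- aperm(a, c(2, 1, 3))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Read a dermoscopic image
#'
#' Reads a PNG, JPEG or TIFF file into the package's canonical representation:
#' an H x W x 3 numeric array with values in `[0, 1]`. Greyscale images are
#' promoted to three identical channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
read_lesion_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .from_ebimage(EBImage::readImage(path))
}

#' Write an image (or binary mask) as PNG
#'
#' @param x H x W x 3 array in `[0, 1]`, or a logical/0-1 matrix (written as
#'   an 8-bit mask, foreground 255).
#' @param path output path.
#' @export
write_lesion_png <- function(x, path) {
  if (is.matrix(x)) {
    EBImage::writeImage(EBImage::Image(t(x * 1)), path, type = "png")
  } else {
    .check_rgb(x)
    EBImage::writeImage(.to_ebimage(x), path, type = "png")
  }
  invisible(path)
}

.resize_rgb <- function(image, h, w) {
  out <- .from_ebimage(EBImage::resize(.to_ebimage(image), w = w, h = h,
                                       filter = "bilinear"))
  out
}

#' Rescale so the maximal dimension equals a target size
#'
#' Bilinear rescaling preserving aspect ratio; the non-maximal dimension is
#' rounded half-up. Images smaller than the target are upscaled, keeping the
#' spatial scale of downstream analysis uniform.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param target target size of the larger dimension (default 1000).
#' @return Rescaled H x W x 3 array with `max(dim) == target`.
#' @export
rescale_max_dim <- function(image, target = 1000L) {
  .check_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < 2L || w < 2L) stop("invalid input: empty or single-pixel image")
  target <- as.integer(target)
  if (target < 2L) stop("target must be >= 2")
  if (max(h, w) == target) return(image)
  s <- target / max(h, w)
  round_half_up <- function(x) floor(x + 0.5)
  if (h >= w) {
    nh <- target; nw <- max(1L, as.integer(round_half_up(w * s)))
  } else {
    nw <- target; nh <- max(1L, as.integer(round_half_up(h * s)))
  }
  .resize_rgb(image, nh, nw)
}

#' Crop to the lesion bounding box and square up to a canonical frame
#'
#' Crops the image to the tight bounding box of the segmentation mask, pads
#' the shorter dimension symmetrically with blank (zero-valued, black) pixels
#' to a square, then bilinearly resamples to `side x side`. Blank pixels are
#' not masked out downstream.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mask logical (or 0/1) H x W matrix, the lesion mask.
#' @param side output side length (default 512).
#' @param pad_then_resize if `TRUE` (default) pad the crop to a square and
#'   resample once to `side`; if `FALSE`, resample the crop so its longer side
#'   equals `side` and then pad, avoiding a second interpolation of lesion
#'   pixels.
#' @return `side x side x 3` array.
#' @export
crop_pad_square <- function(image, mask, side = 512L, pad_then_resize = TRUE) {
  .check_rgb(image)
  mask <- mask > 0
  if (!identical(dim(mask), dim(image)[1:2]))
    stop("mask dimensions must match the image")
  if (!any(mask)) stop("segmentation failure: empty mask")
  side <- as.integer(side)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  crop <- image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  pad_square <- function(x) {
    h <- dim(x)[1]; w <- dim(x)[2]
    if (h == w) return(x)
    d <- abs(h - w); before <- d %/% 2L; after <- d - before
    out <- array(0, c(max(h, w), max(h, w), 3L))
    if (h < w) out[(before + 1L):(before + h), , ] <- x
    else out[, (before + 1L):(before + w), ] <- x
    out
  }
  if (pad_then_resize) {
    sq <- pad_square(crop)
    if (dim(sq)[1] == side) sq else .resize_rgb(sq, side, side)
  } else {
    h <- dim(crop)[1]; w <- dim(crop)[2]
    s <- side / max(h, w)
    nh <- max(1L, as.integer(floor(h * s + 0.5)))
    nw <- max(1L, as.integer(floor(w * s + 0.5)))
    if (h >= w) nh <- side else nw <- side
    pad_square(.resize_rgb(crop, nh, nw))
  }
}

#' Preprocess a dermoscopic image to the canonical analysis frame
#'
#' The full preprocessing chain: rescale so the maximal dimension is `target`
#' pixels, segment the lesion with the Chan-Vese active contour
#' ([segment_chan_vese()]), crop to the lesion bounding box, square up with
#' blank pixels and resample to `side x side`. Segmentation runs at a reduced
#' working resolution (`seg_maxdim`) and the mask is upsampled to the analysis
#' frame; contour precision at the full frame is immaterial after the final
#' resample.
#'
#' @param image H x W x 3 array in `[0, 1]`, or a file path.
#' @param target rescale target for the maximal dimension (default 1000).
#' @param side canonical frame side (default 512).
#' @param params [chan_vese_params()] for segmentation.
#' @param seg_maxdim working resolution for segmentation (default 256).
#' @param pad_then_resize see [crop_pad_square()].
#' @return A list of class `preprocessed_lesion`: `frame` (`side x side x 3`),
#'   `mask` (lesion mask at the rescaled resolution), `bbox`
#'   (`c(row1, row2, col1, col2)`).
#' @export
preprocess_image <- function(image, target = 1000L, side = 512L,
                             params = chan_vese_params(),
                             seg_maxdim = 256L, pad_then_resize = TRUE) {
  if (is.character(image)) image <- read_lesion_image(image)
  big <- rescale_max_dim(image, target)
  small <- if (max(dim(big)[1:2]) > seg_maxdim)
    rescale_max_dim(big, seg_maxdim) else big
  m <- segment_chan_vese(small, params)
  if (!identical(dim(m), dim(big)[1:2])) {
    mi <- EBImage::resize(EBImage::Image(t(m * 1)),
                          w = dim(big)[2], h = dim(big)[1],
                          filter = "bilinear")
    m <- t(as.array(mi)) > 0.5
  }
  if (!any(m)) stop("segmentation failure: empty mask")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  frame <- crop_pad_square(big, m, side, pad_then_resize)
  out <- list(frame = frame, mask = m,
              bbox = c(rows[1], rows[2], cols[1], cols[2]))
  class(out) <- "preprocessed_lesion"
  out
}

#' @export
print.preprocessed_lesion <- function(x, ...) {
  d <- dim(x$frame)
  cat(sprintf("Preprocessed lesion: %dx%dx%d frame, lesion bbox [%d:%d, %d:%d]\n",
              d[1], d[2], d[3], x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}
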