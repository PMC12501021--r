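#' @importFrom stats rnorm runif median pchisq pbinom setNames
#' @importFrom utils read.csv write.csv
NULL

# Raster images are plain numeric arrays in [0, 255]:
#   grayscale -> H x W matrix, RGB -> H x W x 3 array.
# Row 1 is the top image row; this matches the matrix convention used
# throughout (EBImage's width-first layout is converted at the IO boundary).

#' Validate and coerce a raster image
#'
#' A raster image is a numeric `H x W` matrix (grayscale) or `H x W x 3`
#' array (RGB) with finite intensities in \[0, 255\].
#'
#' @param x Numeric matrix or 3-d array.
#' @param clip If `TRUE`, clip values into \[0, 255\] instead of erroring.
#' @return The validated image (invisibly unchanged apart from clipping).
#' @export
as_raster <- function(x, clip = FALSE) {
  if (!is.numeric(x)) stop("raster image must be numeric")
  d <- dim(x)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L))))
    stop("raster image must be H x W or H x W x {1,3}")
  if (length(d) == 3L && d[3] == 1L) {
    x <- array(x, d[1:2])
    d <- dim(x)
  }
  if (any(d[1:2] < 1L)) stop("raster image must have H, W >= 1")
  if (!all(is.finite(x))) stop("raster image contains non-finite values")
  if (clip) x <- pmin(pmax(x, 0), 255)
  if (min(x) < 0 || max(x) > 255) stop("raster intensities must lie in [0, 255]")
  x
}

#' Number of channels of a raster image
#' @param img Raster image.
#' @return 1 for grayscale, 3 for RGB.
#' @export
n_channels <- function(img) if (length(dim(img)) == 2L) 1L else dim(img)[3]

#' Convert an RGB raster image to luminance grayscale
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B. Grayscale
#' input is returned unchanged.
#'
#' @param img Raster image.
#' @return `H x W` matrix in \[0, 255\].
#' @export
to_gray <- function(img) {
  if (n_channels(img) == 1L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read a PNG/JPEG image as a raster image
#' @param path File path.
#' @return Raster image in \[0, 255\].
#' @export
read_image <- function(path) {
  x <- EBImage::imageData(EBImage::readImage(path))
  # EBImage is width-first; transpose to H x W(, C)
  x <- if (length(dim(x)) == 2L) t(x) else aperm(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(2, 1, 3))
  as_raster(x * 255, clip = TRUE)
}

#' Write a raster image as PNG or JPEG
#' @param img Raster image.
#' @param path Output path; format chosen from the file extension.
#' @export
write_image <- function(img, path) {
  img <- as_raster(img, clip = TRUE) / 255
  x <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(x, colormode = if (length(dim(img)) == 2L) "Grayscale" else "Color"), path)
  invisible(path)
}

#' Write a binary mask as a single-channel PNG with values {0, 255}
#' @param mask Binary `H x W` matrix in {0, 1}.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 1)))
  write_image(mask * 255, path)
}

# Reflect-pad a matrix by p pixels on each side (p < dim allows standard
# reflection without repeating the border pixel's mirror ambiguity; we use
# "symmetric" reflection: row p+1-k maps to row k).
pad_reflect <- function(m, p) {
  if (p == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  if (p >= h || p >= w) stop("padding exceeds image size")
  ri <- c(p:1, 1:h, h:(h - p + 1))
  ci <- c(p:1, 1:w, w:(w - p + 1))
  m[ri, ci, drop = FALSE]
}

# Apply a function channel-wise, preserving gray/RGB structure.
per_channel <- function(img, f) {
  if (n_channels(img) == 1L) return(f(img))
  out <- img
  for (k in 1:3) out[, , k] <- f(img[, , k])
  out
}

#' Bilinear image resize
#'
#' Resamples with bilinear interpolation on the pixel-center grid; used to
#' map images onto the fixed input resolutions of the two model branches.
#'
#' @param img Raster image.
#' @param h,w Target height and width in pixels.
#' @return Resized raster image.
#' @export
resize_image <- function(img, h, w) {
  stopifnot(h >= 1, w >= 1)
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  resize_mat <- function(m) {
    H <- nrow(m); W <- ncol(m)
    # map target pixel centers onto source coordinates
    ys <- (seq_len(h) - 0.5) * H / h + 0.5 - 0.5
    xs <- (seq_len(w) - 0.5) * W / w + 0.5 - 0.5
    ys <- pmin(pmax(ys, 1), H); xs <- pmin(pmax(xs, 1), W)
    y0 <- pmin(floor(ys), H - 1L); x0 <- pmin(floor(xs), W - 1L)
    if (H == 1L) y0 <- rep(1, h)
    if (W == 1L) x0 <- rep(1, w)
    fy <- ys - y0; fx <- xs - x0
    y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
    m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
    m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
    FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
    m00 * (1 - FY) * (1 - FX) + m01 * (1 - FY) * FX + m10 * FY * (1 - FX) + m11 * FY * FX
  }
  out <- if (n_channels(img) == 1L) resize_mat(img) else {
    a <- array(0, c(h, w, 3))
    for (k in 1:3) a[, , k] <- resize_mat(img[, , k])
    a
  }
  as_raster(out, clip = TRUE)
}
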