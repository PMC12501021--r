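# Dermoscopy preprocessing: adaptive local-statistics smoothing, Laplacian
# sharpening, morphological hair detection and inverse-distance inpainting.

#' Enhancement configuration
#'
#' @param window Odd local-statistics window side in pixels (>= 3).
#' @param noise_var Assumed noise variance (intensity^2), or `"auto"` to
#'   estimate it with [estimate_noise_variance()].
#' @param kernel Discrete 3x3 Laplacian variant: `"eight-neighbor"`
#'   (center -8) or `"four-neighbor"` (center -4).
#' @param clip_range Output clipping range, default `c(0, 255)`.
#' @return A list of class `enhancement_config`.
#' @export
enhancement_config <- function(window = 7L, noise_var = "auto",
                               kernel = c("eight-neighbor", "four-neighbor"),
                               clip_range = c(0, 255)) {
  kernel <- match.arg(kernel)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (!identical(noise_var, "auto")) {
    if (!is.numeric(noise_var) || length(noise_var) != 1L || noise_var < 0)
      stop("noise_var must be a nonnegative scalar or \"auto\"")
  }
  stopifnot(length(clip_range) == 2L, clip_range[1] < clip_range[2])
  structure(list(window = window, noise_var = noise_var, kernel = kernel,
                 clip_range = clip_range), class = "enhancement_config")
}

#' Hair-removal configuration
#'
#' @param se_length Length in pixels of the linear structuring element
#'   (odd, >= 3). Defaults to 17, a common choice for dermoscopy hair
#'   widths at typical resolutions.
#' @param n_orientations Number of structuring-element orientations spread
#'   uniformly over \[0, 180) degrees.
#' @param mask_threshold `"otsu"` or a fixed numeric threshold applied to
#'   the closing residual (intensity units).
#' @param dilation_radius Binary dilation radius applied to the detected
#'   mask, in pixels (0 disables).
#' @param inpaint_min_neighbors Minimum number of non-hair donor pixels an
#'   inpainting window must contain before the weighted mean is taken.
#' @return A list of class `hair_removal_config`.
#' @export
hair_removal_config <- function(se_length = 17L, n_orientations = 8L,
                                mask_threshold = "otsu", dilation_radius = 1L,
                                inpaint_min_neighbors = 4L) {
  se_length <- as.integer(se_length)
  if (se_length < 3L) stop("se_length must be >= 3")
  if (se_length %% 2L == 0L) se_length <- se_length + 1L
  if (n_orientations < 1L) stop("n_orientations must be >= 1")
  if (!identical(mask_threshold, "otsu") &&
      !(is.numeric(mask_threshold) && length(mask_threshold) == 1L))
    stop("mask_threshold must be \"otsu\" or a numeric scalar")
  if (inpaint_min_neighbors < 1L) stop("inpaint_min_neighbors must be >= 1")
  structure(list(se_length = se_length, n_orientations = as.integer(n_orientations),
                 mask_threshold = mask_threshold,
                 dilation_radius = as.integer(dilation_radius),
                 inpaint_min_neighbors = as.integer(inpaint_min_neighbors)),
            class = "hair_removal_config")
}

# O(1)-per-pixel box sums on a reflect-padded matrix via 2-d cumulative sums.
box_sum <- function(m, w) {
  p <- (w - 1L) %/% 2L
  mp <- pad_reflect(m, p)
  cs <- apply(mp, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  H <- nrow(m); W <- ncol(m)
  cs <- rbind(0, cbind(0, cs))
  a <- cs[(w + 1):(w + H), (w + 1):(w + W), drop = FALSE]
  b <- cs[1:H, (w + 1):(w + W), drop = FALSE]
  cc <- cs[(w + 1):(w + H), 1:W, drop = FALSE]
  d <- cs[1:H, 1:W, drop = FALSE]
  a - b - cc + d
}

local_stats <- function(m, w) {
  n <- w * w
  mu <- box_sum(m, w) / n
  v <- box_sum(m * m, w) / n - mu * mu
  v[v < 0] <- 0  # numerical guard
  list(mean = mu, var = v)
}

#' Estimate the noise variance of an image
#'
#' The noise variance is taken as the median of the local-variance map
#' computed over `w x w` windows (reflect-padded), a robust estimate that
#' is insensitive to lesion structure occupying a minority of windows.
#' RGB images are handled per channel and the channel medians averaged.
#'
#' @param img Raster image.
#' @param w Odd window side in pixels.
#' @return Nonnegative scalar noise variance (intensity^2).
#' @export
estimate_noise_variance <- function(img, w = 7L) {
  img <- as_raster(img)
  w <- as.integer(w)
  if (w %% 2L == 0L || w < 3L) stop("w must be odd and >= 3")
  d <- dim(img)
  if (d[1] < w || d[2] < w) stop("image smaller than the local window")
  meds <- if (n_channels(img) == 1L) median(local_stats(img, w)$var)
  else vapply(1:3, function(k) median(local_stats(img[, , k], w)$var), 0)
  mean(meds)
}

#' Adaptive average filter
#'
#' Local-statistics smoothing: each pixel is pulled towards its local mean
#' by an amount governed by the ratio of (local variance - noise variance)
#' to local variance. Where the local variance is at the noise floor the
#' pixel is replaced by the local mean (full smoothing); where it greatly
#' exceeds it, the pixel is preserved (edges). The ratio is clamped to
#' \[0, 1\] so the output is always a convex combination of the pixel and
#' its local mean; zero local variance is treated as ratio 0.
#'
#' @param img Raster image.
#' @param noise_var Assumed noise variance (>= 0).
#' @param w Odd window side.
#' @return Filtered raster image, same shape.
#' @export
adaptive_average_filter <- function(img, noise_var, w = 7L) {
  img <- as_raster(img)
  if (!is.numeric(noise_var) || noise_var < 0) stop("noise_var must be >= 0")
  w <- as.integer(w)
  if (w %% 2L == 0L || w < 3L) stop("w must be odd and >= 3")
  filt <- function(m) {
    s <- local_stats(m, w)
    ratio <- ifelse(s$var > 0, (s$var - noise_var) / s$var, 0)
    ratio <- pmin(pmax(ratio, 0), 1)
    s$mean + ratio * (m - s$mean)
  }
  per_channel(img, filt)
}

laplacian_kernels <- list(
  "four-neighbor"  = matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
  "eight-neighbor" = matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
)

#' Discrete Laplacian filter
#'
#' Convolves the image with a 3x3 discrete Laplacian (second-derivative)
#' kernel under reflect padding. The response is signed and is not
#' clipped; constant and linear-ramp regions give a zero response.
#'
#' @param img Raster image (or any numeric matrix/array).
#' @param kernel `"eight-neighbor"` (center -8) or `"four-neighbor"`.
#' @return Signed response map with the shape of `img`.
#' @export
laplacian_filter <- function(img, kernel = c("eight-neighbor", "four-neighbor")) {
  kernel <- match.arg(kernel)
  k <- laplacian_kernels[[kernel]]
  conv3 <- function(m) {
    mp <- pad_reflect(m, 1L)
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      # symmetric kernel: convolution == correlation
      out <- out + k[dy + 2, dx + 2] * mp[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    }
    out
  }
  per_channel(img, conv3)
}

#' Enhance a dermoscopic image
#'
#' Two-stage enhancement: adaptive average smoothing followed by Laplacian
#' sharpening of the smoothed result, fused by element-wise addition and
#' clipped to the configured range. RGB images are processed per channel.
#'
#' @param img Raster image.
#' @param cfg [enhancement_config()].
#' @return Enhanced raster image.
#' @export
enhance_image <- function(img, cfg = enhancement_config()) {
  stopifnot(inherits(cfg, "enhancement_config"))
  img <- as_raster(img)
  nv <- if (identical(cfg$noise_var, "auto")) estimate_noise_variance(img, cfg$window) else cfg$noise_var
  adap <- adaptive_average_filter(img, nv, cfg$window)
  lap <- laplacian_filter(adap, cfg$kernel)
  out <- adap + lap
  pmin(pmax(out, cfg$clip_range[1]), cfg$clip_range[2])
}

# Grayscale morphological closing with a linear structuring element at a
# given angle (degrees). Offsets are the SE's pixel coordinates; reflect
# padding avoids dark-border false positives.
line_offsets <- function(len, angle_deg) {
  r <- (len - 1) / 2
  th <- angle_deg * pi / 180
  t <- seq(-r, r, by = 1)
  dy <- round(t * sin(th)); dx <- round(t * cos(th))
  unique(cbind(dy, dx))
}

shift_mat <- function(mp, dy, dx, p, H, W) {
  mp[(p + 1 + dy):(p + H + dy), (p + 1 + dx):(p + W + dx), drop = FALSE]
}

gray_close_line <- function(m, len, angle_deg) {
  off <- line_offsets(len, angle_deg)
  p <- as.integer(max(abs(off)))
  H <- nrow(m); W <- ncol(m)
  mp <- pad_reflect(m, p)
  dil <- matrix(-Inf, H, W)
  for (i in seq_len(nrow(off))) dil <- pmax(dil, shift_mat(mp, off[i, 1], off[i, 2], p, H, W))
  dp <- pad_reflect(dil, p)
  ero <- matrix(Inf, H, W)
  for (i in seq_len(nrow(off))) ero <- pmin(ero, shift_mat(dp, -off[i, 1], -off[i, 2], p, H, W))
  ero
}

#' Detect a hair mask
#'
#' Hairs appear as thin dark elongated curves. For each of
#' `n_orientations` linear structuring elements the grayscale closing is
#' computed; the per-pixel maximum of the closings minus the original
#' luminance forms a residual that is large exactly on thin dark linear
#' structure. The residual is thresholded (Otsu by default) and the mask
#' dilated to cover hair borders.
#'
#' @param img Raster image (RGB is converted to luminance internally).
#' @param cfg [hair_removal_config()].
#' @return Binary `H x W` matrix in {0, 1}.
#' @export
detect_hair_mask <- function(img, cfg = hair_removal_config()) {
  stopifnot(inherits(cfg, "hair_removal_config"))
  g <- to_gray(as_raster(img))
  if (cfg$se_length > min(dim(g))) stop("se_length exceeds image size")
  angles <- seq(0, 180, length.out = cfg$n_orientations + 1L)[seq_len(cfg$n_orientations)]
  closed <- matrix(-Inf, nrow(g), ncol(g))
  for (a in angles) closed <- pmax(closed, gray_close_line(g, cfg$se_length, a))
  residual <- pmax(closed - g, 0)
  thr <- if (identical(cfg$mask_threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(residual / 255), range = c(0, 1)) * 255
  } else cfg$mask_threshold
  mask <- (residual > thr) * 1
  if (cfg$dilation_radius > 0L) {
    brush <- EBImage::makeBrush(2L * cfg$dilation_radius + 1L, shape = "disc")
    mask <- (EBImage::imageData(EBImage::dilate(EBImage::Image(mask), brush)) > 0) * 1
  }
  matrix(as.numeric(mask), nrow(g), ncol(g))
}

#' Inpaint hair pixels by inverse-distance weighting
#'
#' Every masked pixel is replaced by the weighted mean of non-hair pixels
#' in a square window centred on it, with weights proportional to the
#' inverse Euclidean distance. The window grows until at least
#' `inpaint_min_neighbors` donor pixels are available. Unmasked pixels are
#' returned bit-identical; donors are always original (pre-inpainting)
#' values.
#'
#' @param img Raster image.
#' @param mask Binary `H x W` matrix, 1 = hair.
#' @param cfg [hair_removal_config()].
#' @return Inpainted raster image.
#' @export
inpaint_hair <- function(img, mask, cfg = hair_removal_config()) {
  img <- as_raster(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (!all(dim(mask) == c(H, W))) stop("mask shape must match image")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (all(mask == 1)) stop("mask covers the whole image: no donor pixels")
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(img)
  out <- img
  nc <- n_channels(img)
  getpx <- function(i, j) if (nc == 1L) img[i, j] else img[i, j, ]
  for (q in seq_len(nrow(idx))) {
    y <- idx[q, 1]; x <- idx[q, 2]
    r <- 1L
    repeat {
      ys <- max(1L, y - r):min(H, y + r)
      xs <- max(1L, x - r):min(W, x + r)
      sub <- mask[ys, xs, drop = FALSE]
      donors <- which(sub == 0, arr.ind = TRUE)
      if (nrow(donors) >= cfg$inpaint_min_neighbors) break
      if (length(ys) == H && length(xs) == W) break  # whole image reached
      r <- r + 1L
    }
    dy <- ys[donors[, 1]] - y; dx <- xs[donors[, 2]] - x
    wgt <- 1 / sqrt(dy^2 + dx^2)
    if (nc == 1L) {
      vals <- img[cbind(ys[donors[, 1]], xs[donors[, 2]])]
      out[y, x] <- sum(wgt * vals) / sum(wgt)
    } else {
      for (k in 1:3) {
        vals <- img[cbind(ys[donors[, 1]], xs[donors[, 2]], k)]
        out[y, x, k] <- sum(wgt * vals) / sum(wgt)
      }
    }
  }
  out
}

#' Full preprocessing pipeline
#'
#' Runs enhancement, hair detection on the enhanced image, and inpainting,
#' in that order. Deterministic for fixed inputs and configurations.
#'
#' @param img Raster image.
#' @param e_cfg [enhancement_config()].
#' @param h_cfg [hair_removal_config()].
#' @return List with `image` (final raster image), `mask` (binary hair
#'   mask) and `enhanced` (the intermediate enhanced image).
#' @export
preprocess_pipeline <- function(img, e_cfg = enhancement_config(),
                                h_cfg = hair_removal_config()) {
  enh <- enhance_image(img, e_cfg)
  mask <- detect_hair_mask(enh, h_cfg)
  list(image = inpaint_hair(enh, mask, h_cfg), mask = mask, enhanced = enh)
}
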