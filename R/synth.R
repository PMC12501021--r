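# Synthetic dermoscopy generator: class-conditioned elliptical lesions with
# irregular boundaries on a skin-toned background, optional dark hair
# strokes with exact truth masks, and labeled dataset manifests. Used so
# the whole pipeline is testable offline; see the methods vignette for
# what these fixtures do and do not emulate.

#' Seven-class label set
#'
#' The HAM10000/ISIC-2018 class codes in alphabetical order; integer
#' labels 0..6 used throughout map onto this vector (label + 1).
#' @export
lesion_classes <- c("AKIEC", "BCC", "BKL", "DF", "MEL", "NV", "VASC")

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards, so generators are pure functions of their seed.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Lesion specification
#'
#' Each class occupies a disjoint hue band of width 1/7 on the HSV hue
#' circle (band k = \[k/7, (k+1)/7) for class id k), which makes the seven
#' classes linearly separable in mean-colour space by construction - the
#' property the desk-scale learnability checks rely on.
#'
#' @param class_id Integer 0..6.
#' @param skin_tone Background RGB triple in \[0, 255\].
#' @param size_fraction Lesion area as a fraction of the canvas, in (0, 0.6].
#' @param irregularity Boundary-irregularity amplitude (0 = smooth ellipse).
#' @param noise_sd Additive Gaussian pixel noise, intensity units.
#' @param edge_px Width of the soft alpha-blended lesion edge in pixels.
#' @return List of class `lesion_spec` (includes the derived `hue_band`).
#' @export
lesion_spec <- function(class_id, skin_tone = c(224, 172, 150),
                        size_fraction = 0.25, irregularity = 0.12,
                        noise_sd = 3, edge_px = 1.5) {
  class_id <- as.integer(class_id)
  stopifnot(class_id >= 0L, class_id <= 6L,
            size_fraction > 0, size_fraction <= 0.6, noise_sd >= 0,
            edge_px > 0)
  structure(list(class_id = class_id, skin_tone = skin_tone,
                 hue_band = c(class_id / 7, (class_id + 1) / 7),
                 size_fraction = size_fraction,
                 irregularity = irregularity, noise_sd = noise_sd,
                 edge_px = edge_px),
            class = "lesion_spec")
}

#' Generate a synthetic lesion image
#'
#' Renders an irregular ellipse filled with a saturated colour whose hue
#' is drawn from the class's band, alpha-blended onto a skin-toned
#' background with a soft 1.5 px edge, plus Gaussian noise. Reproducible:
#' the output is a pure function of `(spec, size, seed)`.
#'
#' @param spec [lesion_spec()].
#' @param size `c(H, W)` canvas in pixels (min dimension >= 16).
#' @param seed Integer seed.
#' @return List with `image` (RGB raster), `mask` (binary lesion truth
#'   mask) and `spec`.
#' @export
generate_lesion_image <- function(spec, size = c(64, 64), seed = 1L) {
  stopifnot(inherits(spec, "lesion_spec"))
  H <- size[1]; W <- size[2]
  if (min(H, W) < 16) stop("canvas too small for a lesion")
  with_local_seed(seed, {
    # lesion colour: hue from the class band (kept off the band edges),
    # high saturation so blending/noise cannot move the mean hue out
    hue <- spec$hue_band[1] + (0.3 + 0.4 * runif(1)) / 7
    col <- grDevices::hsv(hue, 0.75 + 0.15 * runif(1), 0.45 + 0.15 * runif(1))
    rgbv <- as.numeric(grDevices::col2rgb(col))
    cy <- H / 2 + runif(1, -H * 0.05, H * 0.05)
    cx <- W / 2 + runif(1, -W * 0.05, W * 0.05)
    aspect <- runif(1, 0.8, 1.25)
    r0 <- sqrt(spec$size_fraction * H * W / (pi * aspect)) # so pi*(r0*aspect)*r0 = frac*H*W
    ph <- runif(3, 0, 2 * pi)
    amp <- spec$irregularity * runif(3, 0.3, 1)
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    u <- (xx - cx) / (r0 * aspect); v <- (yy - cy) / r0
    rho <- sqrt(u^2 + v^2); th <- atan2(v, u)
    bound <- 1 + amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2]) +
      amp[3] * sin(5 * th + ph[3])
    edge <- spec$edge_px / r0
    alpha <- pmin(pmax((bound - rho) / edge, 0), 1)
    # mild illumination gradient over the skin background
    grad <- outer(seq(-1, 1, length.out = H), seq(-1, 1, length.out = W),
                  function(a, b) a * runif(1, -4, 4) + b * runif(1, -4, 4))
    img <- array(0, c(H, W, 3))
    for (k in 1:3) {
      bg <- spec$skin_tone[k] + grad
      img[, , k] <- bg * (1 - alpha) + rgbv[k] * alpha +
        rnorm(H * W, 0, spec$noise_sd)
    }
    img <- pmin(pmax(img, 0), 255)
    list(image = img, mask = (alpha > 0.5) * 1, spec = spec)
  })
}

#' Hair-stroke specification
#'
#' @param n_strokes Number of hair strokes (>= 0).
#' @param thickness Stroke thickness in pixels (1-3).
#' @param darkness Intensity decrement applied on stroke pixels (> 0
#'   guarantees strokes are darker than their local background).
#' @param curvature Relative Bezier control-point offset (0 = straight).
#' @return List of class `hair_spec`.
#' @export
hair_spec <- function(n_strokes = 5L, thickness = 2L, darkness = 70,
                      curvature = 0.25) {
  stopifnot(n_strokes >= 0L, thickness >= 1L, thickness <= 3L, darkness > 0)
  structure(list(n_strokes = as.integer(n_strokes),
                 thickness = as.integer(thickness),
                 darkness = darkness, curvature = curvature),
            class = "hair_spec")
}

#' Draw synthetic hair strokes on an image
#'
#' Strokes are quadratic Bezier curves spanning the canvas, rasterized at
#' the requested thickness and darkened by `darkness` (clipped at 0). The
#' returned truth mask is exactly the set of modified pixels.
#'
#' @param img Raster image.
#' @param spec [hair_spec()].
#' @param seed Integer seed.
#' @return List with `image` and binary `mask` of stroke support.
#' @export
draw_hairs <- function(img, spec = hair_spec(), seed = 1L) {
  img <- as_raster(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  mask <- matrix(0, H, W)
  if (spec$n_strokes == 0L) return(list(image = img, mask = mask))
  rad <- (spec$thickness - 1) / 2
  offs <- expand.grid(dy = -spec$thickness:spec$thickness,
                      dx = -spec$thickness:spec$thickness)
  offs <- offs[sqrt(offs$dy^2 + offs$dx^2) <= max(rad, 0.5) + 1e-9, , drop = FALSE]
  with_local_seed(seed, {
    for (s in seq_len(spec$n_strokes)) {
      horiz <- runif(1) < 0.5
      if (horiz) {
        p0 <- c(runif(1, 1, H), 1); p2 <- c(runif(1, 1, H), W)
      } else {
        p0 <- c(1, runif(1, 1, W)); p2 <- c(H, runif(1, 1, W))
      }
      mid <- (p0 + p2) / 2
      p1 <- mid + spec$curvature * c(runif(1, -H, H), runif(1, -W, W))
      t <- seq(0, 1, length.out = 3L * (H + W))
      py <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
      px <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
      for (o in seq_len(nrow(offs))) {
        yy <- round(py) + offs$dy[o]; xx <- round(px) + offs$dx[o]
        ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
        mask[cbind(yy[ok], xx[ok])] <- 1
      }
    }
    hit <- which(mask == 1)
    if (n_channels(img) == 1L) {
      img[hit] <- pmax(img[hit] - spec$darkness, 0)
    } else {
      for (k in 1:3) {
        ch <- img[, , k]
        ch[hit] <- pmax(ch[hit] - spec$darkness, 0)
        img[, , k] <- ch
      }
    }
    list(image = img, mask = mask)
  })
}

#' Generate a labeled synthetic dataset
#'
#' @param n_per_class Integer vector of length 7 (counts per class, in the
#'   order of [lesion_classes]); a single number is recycled.
#' @param size `c(H, W)` canvas.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, images are written as PNG
#'   files and the manifest as `manifest.csv` there.
#' @param hair_prob Probability that an image receives hair strokes.
#' @return List with `images` (list of RGB rasters), `labels` (integer
#'   0..6) and `manifest` (data.frame: image_id, label, class, path).
#' @export
generate_dataset <- function(n_per_class, size = c(64, 64), seed = 1L,
                             dir = NULL, hair_prob = 0) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 7L)
  stopifnot(length(n_per_class) == 7L, all(n_per_class >= 0L))
  images <- list(); labels <- integer(0); ids <- character(0)
  i <- 0L
  for (k in 0:6) {
    for (j in seq_len(n_per_class[k + 1])) {
      i <- i + 1L
      s <- (seed * 10007L + k * 1009L + j) %% 2147483647L
      spec <- lesion_spec(k)
      les <- generate_lesion_image(spec, size, s)
      im <- les$image
      if (hair_prob > 0 && with_local_seed(s + 1L, runif(1)) < hair_prob)
        im <- draw_hairs(im, hair_spec(), s + 2L)$image
      images[[i]] <- im
      labels[i] <- k
      ids[i] <- sprintf("syn_%s_%04d", lesion_classes[k + 1], j)
    }
  }
  manifest <- data.frame(image_id = ids, label = labels,
                         class = lesion_classes[labels + 1],
                         path = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (q in seq_along(images)) {
      p <- file.path(dir, paste0(ids[q], ".png"))
      write_image(images[[q]], p)
      manifest$path[q] <- p
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, labels = labels, manifest = manifest)
}
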