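# Class-balancing augmentation planner and materializer. The planner is
# class-agnostic: any label set works, targets are original x factor.

round_half_up <- function(x) floor(x + 0.5)

#' Augmentation factor for a class
#'
#' Factor = round-half-up of `T / N_c`, floored at 1; a class at or above
#' the target (the dominant class) gets factor 1 (no augmentation).
#'
#' @param n_c Original image count of the class (>= 1).
#' @param target Target image count per class.
#' @return Integer factor >= 1.
#' @export
augmentation_factor <- function(n_c, target) {
  if (any(n_c < 1)) stop("class counts must be >= 1")
  f <- ifelse(n_c >= target, 1, pmax(1, round_half_up(target / n_c)))
  as.integer(f)
}

#' Build a class-balancing augmentation plan
#'
#' @param inventory Named integer vector or two-column data.frame
#'   (class, original count).
#' @param target Target per-class count (default 8000).
#' @param overrides Optional named vector of per-class factor overrides
#'   (used where a printed factor is not derivable from the target ratio).
#' @return A data.frame of class `augmentation_plan` with columns
#'   `class`, `original`, `factor`, `target` (target = original x factor).
#' @export
build_plan <- function(inventory, target = 8000L, overrides = NULL) {
  if (is.data.frame(inventory)) {
    cls <- as.character(inventory[[1]]); n <- as.integer(inventory[[2]])
  } else {
    cls <- names(inventory); n <- as.integer(inventory)
  }
  if (is.null(cls) || anyDuplicated(cls)) stop("inventory must have unique class labels")
  if (any(n < 1)) stop("class counts must be >= 1")
  f <- augmentation_factor(n, target)
  if (!is.null(overrides)) {
    if (any(overrides < 1)) stop("factor overrides must be >= 1")
    miss <- setdiff(names(overrides), cls)
    if (length(miss)) stop("override for unknown class: ", paste(miss, collapse = ", "))
    f[match(names(overrides), cls)] <- as.integer(overrides)
  }
  plan <- data.frame(class = cls, original = n, factor = f,
                     target = n * f, stringsAsFactors = FALSE)
  class(plan) <- c("augmentation_plan", "data.frame")
  plan
}

#' Serialize / read an augmentation plan as CSV
#' @param plan An `augmentation_plan`.
#' @param path CSV path.
#' @export
write_plan <- function(plan, path) {
  write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "original", "factor", "target") %in% names(p)))
  class(p) <- c("augmentation_plan", "data.frame")
  p
}

#' Label-preserving transform specification
#'
#' @param kind One of `"hflip"`, `"vflip"`, `"rotate"`, `"zoom"`,
#'   `"brightness"`, `"contrast"`, `"saturation"`.
#' @param param Numeric parameter: degrees for rotate (|theta| <= 30),
#'   scale for zoom (0.9-1.1), gain for the photometric kinds (0.8-1.2).
#'   Flips take no parameter.
#' @return List of class `transform_spec`.
#' @export
transform_spec <- function(kind, param = NULL) {
  kinds <- c("hflip", "vflip", "rotate", "zoom", "brightness", "contrast", "saturation")
  kind <- match.arg(kind, kinds)
  rng <- switch(kind,
    rotate = c(-30, 30), zoom = c(0.9, 1.1),
    brightness = c(0.8, 1.2), contrast = c(0.8, 1.2), saturation = c(0.8, 1.2),
    NULL)
  if (!is.null(rng)) {
    if (is.null(param)) stop(kind, " requires a parameter")
    if (param < rng[1] || param > rng[2])
      stop(kind, " parameter out of the allowed range [", rng[1], ", ", rng[2], "]")
  }
  structure(list(kind = kind, param = param), class = "transform_spec")
}

# Inverse-mapped affine resampling (rotation about centre and/or central
# zoom) with bilinear interpolation and reflect indexing for fill, so the
# canvas size never changes.
affine_sample <- function(img, theta_deg = 0, zoom = 1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- theta_deg * pi / 180
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: rotate by -theta, scale by 1/zoom
  sy <- (cos(th) * yy - sin(th) * xx) / zoom + cy
  sx <- (sin(th) * yy + cos(th) * xx) / zoom + cx
  reflect_idx <- function(v, n) {
    v <- abs(v - 1) %% (2 * (n - 1))
    ifelse(v > (n - 1), 2 * (n - 1) - v, v) + 1
  }
  if (H > 1) sy <- reflect_idx(sy, H) else sy[] <- 1
  if (W > 1) sx <- reflect_idx(sx, W) else sx[] <- 1
  y0 <- pmin(floor(sy), H - 1L); x0 <- pmin(floor(sx), W - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- sy - y0; fx <- sx - x0
  y1 <- pmin(y0 + 1L, H); x1 <- pmin(x0 + 1L, W)
  samp <- function(m) {
    m00 <- m[cbind(as.vector(y0), as.vector(x0))]
    m01 <- m[cbind(as.vector(y0), as.vector(x1))]
    m10 <- m[cbind(as.vector(y1), as.vector(x0))]
    m11 <- m[cbind(as.vector(y1), as.vector(x1))]
    matrix(m00 * (1 - fy) * (1 - fx) + m01 * (1 - fy) * fx +
             m10 * fy * (1 - fx) + m11 * fy * fx, H, W)
  }
  per_channel(img, samp)
}

#' Apply a label-preserving transform
#'
#' Geometric kinds resample on the same canvas (reflection fill);
#' photometric kinds rescale intensities and clip. Deterministic: the
#' transform itself draws no randomness.
#'
#' @param img Raster image.
#' @param spec [transform_spec()].
#' @return Transformed raster image, same shape and scale.
#' @export
apply_transform <- function(img, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  img <- as_raster(img)
  out <- switch(spec$kind,
    hflip = per_channel(img, function(m) m[, ncol(m):1, drop = FALSE]),
    vflip = per_channel(img, function(m) m[nrow(m):1, , drop = FALSE]),
    rotate = affine_sample(img, theta_deg = spec$param),
    zoom = affine_sample(img, zoom = spec$param),
    brightness = img * spec$param,
    contrast = 127.5 + (img - 127.5) * spec$param,
    saturation = {
      if (n_channels(img) == 1L) img else {
        g <- to_gray(img)
        out <- img
        for (k in 1:3) out[, , k] <- g + (img[, , k] - g) * spec$param
        out
      }
    })
  as_raster(out, clip = TRUE)
}

# Draw a random transform spec from the configured parameter ranges.
draw_transform_spec <- function() {
  kind <- sample(c("hflip", "vflip", "rotate", "zoom", "brightness",
                   "contrast", "saturation"), 1)
  param <- switch(kind,
    rotate = runif(1, -30, 30), zoom = runif(1, 0.9, 1.1),
    brightness = runif(1, 0.8, 1.2), contrast = runif(1, 0.8, 1.2),
    saturation = runif(1, 0.8, 1.2), NULL)
  transform_spec(kind, param)
}

#' Materialize a balanced dataset
#'
#' Each class ends with exactly `target = original x factor` images: the
#' originals plus `(factor - 1)` augmented variants of each original,
#' every variant tracing to its parent id. Fully reproducible for a fixed
#' seed.
#'
#' @param dataset List with `images` (list of rasters), `labels` (integer
#'   0..6 or character class codes) and optionally `manifest` with
#'   `image_id`; as produced by [generate_dataset()].
#' @param plan [build_plan()] result; must cover every class present.
#' @param seed Integer seed.
#' @return List with `images`, `labels`, and `manifest` (image_id, label,
#'   class, parent_id).
#' @export
materialize_balanced_dataset <- function(dataset, plan, seed = 1L) {
  labels <- dataset$labels
  cls <- if (is.numeric(labels)) lesion_classes[labels + 1] else as.character(labels)
  miss <- setdiff(unique(cls), plan$class)
  if (length(miss)) stop("classes missing from plan: ", paste(miss, collapse = ", "))
  ids <- if (!is.null(dataset$manifest$image_id)) dataset$manifest$image_id
  else sprintf("img_%04d", seq_along(dataset$images))
  out_img <- list(); out_lab <- integer(0); out_id <- character(0); out_par <- character(0)
  n_out <- 0L
  with_local_seed(seed, {
    for (i in seq_along(dataset$images)) {
      f <- plan$factor[match(cls[i], plan$class)]
      n_out <- n_out + 1L
      out_img[[n_out]] <- dataset$images[[i]]
      out_lab[n_out] <- labels[i]; out_id[n_out] <- ids[i]; out_par[n_out] <- NA_character_
      if (f > 1L) for (r in seq_len(f - 1L)) {
        n_out <- n_out + 1L
        out_img[[n_out]] <- apply_transform(dataset$images[[i]], draw_transform_spec())
        out_lab[n_out] <- labels[i]
        out_id[n_out] <- paste0(ids[i], "_aug", r)
        out_par[n_out] <- ids[i]
      }
    }
    list(images = out_img, labels = out_lab,
         manifest = data.frame(image_id = out_id, label = out_lab,
                               class = if (is.numeric(out_lab)) lesion_classes[out_lab + 1] else out_lab,
                               parent_id = out_par, stringsAsFactors = FALSE))
  })
}

#' The printed training-set inventory used for the worked balancing example
#'
#' Eight-class training inventory (including SCC) with the printed
#' per-class factors; the BCC row's printed product is internally
#' inconsistent and is reproduced here only as printed input, see docs.
#' @return data.frame with class, original, printed factor.
#' @export
ham_training_inventory <- function() {
  data.frame(
    class = c("DF", "VASC", "AKIEC", "SCC", "BCC", "BKL", "MEL", "NV"),
    original = c(153L, 162L, 555L, 402L, 212L, 1679L, 2894L, 8240L),
    printed_factor = c(52L, 52L, 14L, 20L, 64L, 5L, 3L, 1L),
    stringsAsFactors = FALSE)
}
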