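# Convolution, pooling and dense layers over the autodiff core.
#
# Feature maps are stored as (H*W) x C matrices with column-major spatial
# vectorization (pixel s = y + (x-1)*H). Convolutions use im2col: a
# gather into a (H'W') x (k^2 C) matrix followed by a matrix product with
# the (k^2 C) x Cout weight. Weight-column order is (channel, kx, ky)
# with ky fastest, matching the index builder.

im2col_index <- function(H, W, C, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  cached <- the$im2col[[key]]
  if (!is.null(cached)) return(cached)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  iy0 <- (oy - 1L) * stride - pad
  ix0 <- (ox - 1L) * stride - pad
  idx <- matrix(0L, Ho * Wo, k * k * C)
  col <- 0L
  for (c in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    col <- col + 1L
    y <- iy0 + ky; x <- ix0 + kx
    inside <- y >= 1L & y <= H & x >= 1L & x <= W
    v <- integer(Ho * Wo)
    v[inside] <- (c - 1L) * H * W + (x[inside] - 1L) * H + y[inside]
    idx[, col] <- v
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  assign(key, out, envir = the$im2col)
  out
}

# He-normal conv weight init; biases zero. Draws from the current RNG
# stream (callers seed via with_local_seed).
conv_init <- function(k, c_in, c_out, bias = FALSE) {
  fan_in <- k * k * c_in
  p <- list(W = matrix(rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out))
  if (bias) p$b <- numeric(c_out)
  p
}

dense_init <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

bn_init <- function(c_out) list(gamma = rep(1, c_out), beta = rep(0, c_out))

# x: node of (H*W) x Cin; returns list(node, H, W) of the convolved map.
conv_apply <- function(x, p, H, W, c_in, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L && stride == 1L) {
    out <- ad_matmul(x, p$W)
    Ho <- H; Wo <- W
  } else {
    ic <- im2col_index(H, W, c_in, k, stride, pad)
    cols <- ad_gather_zero(x, ic$idx, dim(ic$idx))
    out <- ad_matmul(cols, p$W)
    Ho <- ic$Ho; Wo <- ic$Wo
  }
  if (!is.null(p$b)) out <- ad_bias(out, p$b)
  list(x = out, H = Ho, W = Wo)
}

dense_apply <- function(x, p) ad_bias(ad_matmul(x, p$W), p$b)

# Max pooling (k x k, stride s, zero-"pad" treated as -Inf so it is never
# selected). Backward scatters gradients to the argmax source pixels.
ad_maxpool <- function(a, H, W, C, k = 3L, stride = 2L, pad = (k - 1L) %/% 2L) {
  a <- as_node(a)
  ic <- im2col_index(H, W, C, k, stride, pad)
  idx <- ic$idx
  n_out <- nrow(idx); kk <- k * k
  v <- c(-Inf, as.vector(a$val))[idx + 1L]
  dim(v) <- dim(idx)
  out <- matrix(0, n_out, C)
  src <- matrix(0L, n_out, C)
  for (c in seq_len(C)) {
    block <- ((c - 1L) * kk + 1L):(c * kk)
    sub <- v[, block, drop = FALSE]
    am <- max.col(sub, ties.method = "first")
    out[, c] <- sub[cbind(seq_len(n_out), am)]
    src[, c] <- idx[, block, drop = FALSE][cbind(seq_len(n_out), am)]
  }
  xd <- dim(a$val); xlen <- length(a$val)
  node <- new_node(out, list(a), function(g) {
    acc <- rowsum(as.vector(g), as.vector(src))
    gr <- numeric(xlen)
    gr[as.integer(rownames(acc))] <- acc
    dim(gr) <- xd
    list(gr)
  })
  list(x = node, H = ic$Ho, W = ic$Wo)
}

# Average pooling (k x k, stride s, no padding); divides by k^2.
ad_avgpool <- function(a, H, W, C, k = 2L, stride = 2L) {
  a <- as_node(a)
  ic <- im2col_index(H, W, C, k, stride, pad = 0L)
  idx <- ic$idx
  kk <- k * k
  v <- c(0, as.vector(a$val))[idx + 1L]
  dim(v) <- dim(idx)
  out <- matrix(0, nrow(idx), C)
  for (c in seq_len(C)) out[, c] <- rowSums(v[, ((c - 1L) * kk + 1L):(c * kk), drop = FALSE]) / kk
  xd <- dim(a$val); xlen <- length(a$val)
  node <- new_node(out, list(a), function(g) {
    gmat <- g[, rep(seq_len(C), each = kk), drop = FALSE] / kk
    keep <- idx > 0L
    acc <- rowsum(as.vector(gmat)[as.vector(keep)], as.vector(idx)[as.vector(keep)])
    gr <- numeric(xlen)
    gr[as.integer(rownames(acc))] <- acc
    dim(gr) <- xd
    list(gr)
  })
  list(x = node, H = ic$Ho, W = ic$Wo)
}

# Convert an H x W x C array (or H x W matrix) to the (H*W) x C layout.
map_to_mat <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  matrix(as.vector(x), d[1] * d[2], d[3])
}

mat_to_map <- function(m, H, W) array(as.vector(m), c(H, W, ncol(m)))
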