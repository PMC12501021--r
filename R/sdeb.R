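# Spatial Detail Enhancement Block: three parallel multi-scale
# convolutions with ReLU whose outputs, aligned to a common channel count
# by 1x1 projections, are summed element-wise and fused by a 1x1
# convolution with ReLU. Applied to patch-token feature maps to restore
# local boundary/texture detail lost in patchification.

#' SDEB configuration
#'
#' @param branches List of exactly three `c(kernel, filters)` pairs;
#'   defaults to the 3x3/64, 5x5/128, 7x7/256 multi-scale trio.
#' @param channels Common fused channel count `C` (default 256). Branch
#'   outputs are aligned to `C` by 1x1 projections before the
#'   element-wise sum (the three branch widths differ, so a direct sum is
#'   undefined without alignment).
#' @return List of class `sdeb_config`.
#' @export
sdeb_config <- function(branches = list(c(3, 64), c(5, 128), c(7, 256)),
                        channels = 256L) {
  if (length(branches) != 3L) stop("SDEB has exactly three branches")
  for (b in branches) stopifnot(length(b) == 2L, b[1] >= 1, b[2] >= 1)
  stopifnot(channels >= 1L)
  structure(list(branches = branches, channels = as.integer(channels)),
            class = "sdeb_config")
}

#' Initialize SDEB weights
#'
#' He-normal weights, zero biases, for the three branch convolutions,
#' their 1x1 channel-alignment projections, and the 1x1 fusion layer.
#'
#' @param cfg [sdeb_config()].
#' @param in_channels Input channel count of the patch-token feature map.
#' @param seed Integer seed.
#' @return Nested list of weight matrices.
#' @export
init_sdeb <- function(cfg, in_channels, seed = 1L) {
  with_local_seed(seed, {
    branches <- lapply(cfg$branches, function(b)
      list(conv = conv_init(b[1], in_channels, b[2], bias = TRUE),
           proj = conv_init(1L, b[2], cfg$channels, bias = TRUE)))
    list(branches = branches,
         fuse = conv_init(1L, cfg$channels, cfg$channels, bias = TRUE))
  })
}

# Graph-building form used by the hybrid model and the training loop.
sdeb_apply <- function(x, params, cfg, H, W, c_in) {
  kmax <- max(vapply(cfg$branches, `[`, 0, 1))
  if (H < kmax || W < kmax)
    stop("SDEB input spatial dims must be >= the largest branch kernel (", kmax, ")")
  acc <- NULL
  for (i in 1:3) {
    k <- cfg$branches[[i]][1]
    f <- ad_relu(conv_apply(x, params$branches[[i]]$conv, H, W, c_in, k)$x)
    f <- conv_apply(f, params$branches[[i]]$proj, H, W, cfg$branches[[i]][2], 1L)$x
    acc <- if (is.null(acc)) f else ad_add(acc, f)
  }
  ad_relu(conv_apply(acc, params$fuse, H, W, cfg$channels, 1L)$x)
}

#' SDEB forward pass
#'
#' @param x Input feature map: an `H x W x C` array, or a token matrix
#'   carrying a `grid` attribute (as returned by [embed_tokens()]), in
#'   which case tokens are reshaped onto their patch grid, convolved, and
#'   returned as tokens again.
#' @param cfg [sdeb_config()].
#' @param weights [init_sdeb()] result.
#' @return Feature map of the same kind as the input with `channels`
#'   output channels; spatial dimensions are preserved.
#' @export
sdeb_forward <- function(x, cfg, weights) {
  tokens_in <- is.matrix(x) && !is.null(attr(x, "grid"))
  if (tokens_in) {
    grid <- attr(x, "grid")
    map <- tokens_to_map(x, grid)
  } else {
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
    map <- x
  }
  H <- dim(map)[1]; W <- dim(map)[2]; C <- dim(map)[3]
  out <- sdeb_apply(ad_const(map_to_mat(map)), weights, cfg, H, W, C)$val
  if (tokens_in) {
    map_to_tokens(mat_to_map(out, H, W), grid)
  } else {
    mat_to_map(out, H, W)
  }
}

# Tokens are row-major over the patch grid (row r, col c -> token
# (r-1)*cols + c); maps are rows x cols x D arrays.
tokens_to_map <- function(tokens, grid) {
  rows <- grid[["rows"]]; cols <- grid[["cols"]]
  stopifnot(nrow(tokens) == rows * cols)
  arr <- array(0, c(rows, cols, ncol(tokens)))
  i <- 0L
  for (r in seq_len(rows)) for (cl in seq_len(cols)) {
    i <- i + 1L
    arr[r, cl, ] <- tokens[i, ]
  }
  arr
}

map_to_tokens <- function(map, grid = NULL) {
  rows <- dim(map)[1]; cols <- dim(map)[2]
  out <- matrix(0, rows * cols, dim(map)[3])
  i <- 0L
  for (r in seq_len(rows)) for (cl in seq_len(cols)) {
    i <- i + 1L
    out[i, ] <- map[r, cl, ]
  }
  attr(out, "grid") <- c(rows = rows, cols = cols)
  out
}

# Permutation taking (H*W) x C column-major map rows to row-major token
# order; used inside the hybrid graph to avoid materializing 3-d arrays.
token_perm <- function(rows, cols) {
  # token i = (r-1)*cols + c ; map row s = r + (c-1)*rows
  r <- rep(seq_len(rows), each = cols)
  cl <- rep(seq_len(cols), times = rows)
  r + (cl - 1L) * rows
}

ad_permute_rows <- function(a, perm) {
  a <- as_node(a)
  inv <- order(perm)
  new_node(a$val[perm, , drop = FALSE], list(a),
           function(g) list(g[inv, , drop = FALSE]))
}
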