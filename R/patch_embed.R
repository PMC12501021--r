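# Patchification of enhanced images into token sequences with fixed
# sinusoidal positional encodings. The default geometry is a 600 x 450
# image cut into 30 x 30 patches -> 300 tokens.

#' Number of non-overlapping square patches
#'
#' @param h,w Image height and width in pixels.
#' @param p Patch side in pixels; must divide both `h` and `w` exactly
#'   (patchify never resizes - resize upstream instead).
#' @return Integer patch count `h * w / p^2`.
#' @export
num_patches <- function(h, w, p) {
  if (h %% p != 0 || w %% p != 0) stop("patch size must divide image dimensions")
  as.integer((h / p) * (w / p))
}

#' Cut an image into non-overlapping square patches
#'
#' Lossless, row-major tiling: patch 1 is the top-left block, patches run
#' left-to-right then top-to-bottom. Each patch is flattened
#' channel-fastest-last: within a patch, pixels run down columns per
#' channel, channels concatenated.
#'
#' @param img Raster image with dimensions divisible by `p`.
#' @param p Patch side in pixels.
#' @return A `patch_grid`: list with `patches` (N x (p*p*C) matrix),
#'   `p`, `grid` (rows, cols) and `channels`.
#' @export
patchify <- function(img, p) {
  img <- as_raster(img)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- n_channels(img)
  n <- num_patches(H, W, p)
  rows <- H %/% p; cols <- W %/% p
  patches <- matrix(0, n, p * p * C)
  arr <- if (C == 1L) array(img, c(H, W, 1)) else img
  i <- 0L
  for (r in seq_len(rows)) for (cl in seq_len(cols)) {
    i <- i + 1L
    block <- arr[((r - 1) * p + 1):(r * p), ((cl - 1) * p + 1):(cl * p), , drop = FALSE]
    patches[i, ] <- as.vector(block)
  }
  structure(list(patches = patches, p = p, grid = c(rows = rows, cols = cols),
                 channels = C), class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of [patchify()]: the round trip is bit-identical.
#'
#' @param grid A `patch_grid`.
#' @return Raster image.
#' @export
unpatchify <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  p <- grid$p; rows <- grid$grid[["rows"]]; cols <- grid$grid[["cols"]]
  C <- grid$channels
  out <- array(0, c(rows * p, cols * p, C))
  i <- 0L
  for (r in seq_len(rows)) for (cl in seq_len(cols)) {
    i <- i + 1L
    out[((r - 1) * p + 1):(r * p), ((cl - 1) * p + 1):(cl * p), ] <-
      array(grid$patches[i, ], c(p, p, C))
  }
  if (C == 1L) out <- array(out, dim(out)[1:2])
  out
}

#' Fixed sinusoidal positional-encoding table
#'
#' Entry `(pos, 2i)` is `sin(pos / base^(2i/D))` and `(pos, 2i+1)` is
#' `cos(pos / base^(2i/D))` for positions `0..N-1` (1-indexed rows). The
#' table is a deterministic function of `(N, D, base)` and is never
#' learned. The default frequency base is 1000.
#'
#' @param n Number of positions (tokens).
#' @param d Embedding dimension (even).
#' @param base Frequency base, default 1000.
#' @return `n x d` matrix with entries in \[-1, 1\].
#' @export
sinusoidal_pe <- function(n, d, base = 1000) {
  if (d %% 2L != 0L) stop("embedding dimension must be even")
  pos <- 0:(n - 1)
  i <- 0:(d / 2 - 1)
  ang <- outer(pos, base^(-2 * i / d))     # n x d/2
  pe <- matrix(0, n, d)
  pe[, 2 * i + 1] <- sin(ang)   # even dims (0-based) -> sine
  pe[, 2 * i + 2] <- cos(ang)   # odd dims (0-based) -> cosine
  pe
}

#' Initialize patch-embedding projection weights
#'
#' He-style Gaussian init for the linear projection from flattened patch
#' pixels to the embedding dimension.
#'
#' @param in_dim Flattened patch length `p*p*C`.
#' @param d Embedding dimension.
#' @param seed Integer seed.
#' @return List with `W` (`in_dim x d`) and `b` (length `d`).
#' @export
init_patch_projection <- function(in_dim, d, seed = 1L) {
  with_local_seed(seed, list(
    W = matrix(rnorm(in_dim * d, 0, sqrt(2 / in_dim)), in_dim, d),
    b = numeric(d)))
}

#' Project patches to tokens and add positional encodings
#'
#' `tokens = patches %*% W + b + PE`. Changing one patch changes only its
#' own token (pre-attention locality).
#'
#' @param grid A `patch_grid` (or bare N x M patch matrix).
#' @param weights Projection from [init_patch_projection()].
#' @param pe Positional-encoding table with N rows ([sinusoidal_pe()]);
#'   `NULL` adds none.
#' @return `token_sequence`: N x D numeric matrix (attribute `grid` keeps
#'   the patch-grid geometry for later spatial reshaping).
#' @export
embed_tokens <- function(grid, weights, pe = NULL) {
  patches <- if (inherits(grid, "patch_grid")) grid$patches else grid
  if (ncol(patches) != nrow(weights$W)) stop("projection input dim mismatch")
  tok <- patches %*% weights$W
  tok <- sweep(tok, 2, weights$b, "+")
  if (!is.null(pe)) {
    if (nrow(pe) != nrow(tok) || ncol(pe) != ncol(tok))
      stop("positional-encoding table shape mismatch")
    tok <- tok + pe
  }
  if (inherits(grid, "patch_grid")) attr(tok, "grid") <- grid$grid
  tok
}
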