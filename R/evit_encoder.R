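# Transformer encoder: multi-head scaled dot-product self-attention with
# layer normalization before and after the attention operation, residual
# connections, and GELU MLPs; six blocks by default.

#' Encoder configuration
#'
#' @param n_blocks Number of sequential encoder blocks (default 6).
#' @param heads Attention heads (default 8); must divide `d`.
#' @param d Token embedding dimension (default 256).
#' @param mlp_ratio Hidden width of the MLP as a multiple of `d`.
#' @param dropout Dropout probability applied after the attention output
#'   projection and inside the MLP during training (0 <= p < 1).
#' @param eps Layer-normalization stabilizer.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(n_blocks = 6L, heads = 8L, d = 256L,
                           mlp_ratio = 4, dropout = 0.1, eps = 1e-6) {
  stopifnot(n_blocks >= 0L, heads >= 1L, d >= 1L, mlp_ratio >= 1,
            dropout >= 0, dropout < 1, eps > 0)
  if (d %% heads != 0L) stop("embedding dimension must be divisible by heads")
  structure(list(n_blocks = as.integer(n_blocks), heads = as.integer(heads),
                 d = as.integer(d), mlp_ratio = mlp_ratio,
                 dropout = dropout, eps = eps), class = "encoder_config")
}

#' Layer normalization
#'
#' Standardizes each row (token) of `x` over the feature dimension:
#' `(x - mean) / sqrt(var + eps)` with population variance; no learned
#' affine terms.
#'
#' @param x Numeric matrix (rows normalized independently) or vector.
#' @param eps Stabilizing constant (> 0).
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, eps = 1e-6) {
  stopifnot(eps > 0)
  if (is.null(dim(x))) return(as.numeric(layer_norm(matrix(x, 1), eps)))
  mu <- rowMeans(x)
  xc <- x - mu
  xc / sqrt(rowMeans(xc * xc) + eps)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`. Every attention row is a probability
#' distribution over the keys (nonnegative, sums to 1).
#'
#' @param Q,K,V Matrices with matching shapes (`N x d_k` for Q and K,
#'   `N x d_v` for V).
#' @param return_weights If `TRUE`, attach the row-stochastic weight
#'   matrix as attribute `"weights"`.
#' @return `N x d_v` matrix.
#' @export
scaled_dot_attention <- function(Q, K, V, return_weights = FALSE) {
  d_k <- ncol(Q)
  if (is.null(d_k) || d_k == 0L) stop("d_k must be positive")
  stopifnot(ncol(K) == d_k, nrow(K) == nrow(V))
  s <- (Q %*% t(K)) / sqrt(d_k)
  m <- apply(s, 1, max)
  e <- exp(s - m)
  A <- e / rowSums(e)
  out <- A %*% V
  if (return_weights) attr(out, "weights") <- A
  out
}

#' Initialize encoder weights
#'
#' Per block: Q/K/V/output projections (`d x d` with biases) and the
#' two-layer GELU MLP (`d -> d*mlp_ratio -> d`). Xavier-scaled Gaussian
#' init, zero biases.
#'
#' @param cfg [encoder_config()].
#' @param seed Integer seed.
#' @return List of per-block weight lists.
#' @export
init_encoder <- function(cfg, seed = 1L) {
  d <- cfg$d; h <- as.integer(round(d * cfg$mlp_ratio))
  with_local_seed(seed, {
    lapply(seq_len(cfg$n_blocks), function(b) list(
      Wq = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bq = numeric(d),
      Wk = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bk = numeric(d),
      Wv = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bv = numeric(d),
      Wo = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bo = numeric(d),
      mlp = list(W1 = matrix(rnorm(d * h, 0, sqrt(2 / d)), d, h), b1 = numeric(h),
                 W2 = matrix(rnorm(h * d, 0, sqrt(2 / h)), h, d), b2 = numeric(d))))
  })
}

# Graph-building multi-head self-attention on an N x D token node.
mhsa_apply <- function(x, p, cfg, training = FALSE) {
  d <- cfg$d; nh <- cfg$heads; dk <- d %/% nh
  Q <- ad_bias(ad_matmul(x, p$Wq), p$bq)
  K <- ad_bias(ad_matmul(x, p$Wk), p$bk)
  V <- ad_bias(ad_matmul(x, p$Wv), p$bv)
  heads <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- ad_slice_cols(Q, cols); Kh <- ad_slice_cols(K, cols); Vh <- ad_slice_cols(V, cols)
    A <- ad_softmax_rows(ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dk)))
    heads[[h]] <- ad_matmul(A, Vh)
  }
  out <- ad_bias(ad_matmul(ad_cbind(heads), p$Wo), p$bo)
  ad_dropout(out, cfg$dropout, training)
}

mlp_apply <- function(x, p, cfg, training = FALSE) {
  h <- ad_gelu(ad_bias(ad_matmul(x, p$W1), p$b1))
  h <- ad_dropout(h, cfg$dropout, training)
  ad_dropout(ad_bias(ad_matmul(h, p$W2), p$b2), cfg$dropout, training)
}

encoder_apply <- function(x, params, cfg, training = FALSE) {
  for (b in seq_len(cfg$n_blocks)) {
    p <- params[[b]]
    a <- ad_layernorm_rows(x, cfg$eps)            # LN before attention
    a <- mhsa_apply(a, p, cfg, training)
    a <- ad_layernorm_rows(a, cfg$eps)            # LN after attention
    x <- ad_add(x, a)                             # residual
    x <- ad_add(x, mlp_apply(x, p$mlp, cfg, training))  # MLP + residual
  }
  x
}

#' Multi-head self-attention (evaluation mode)
#'
#' Splits the projected queries/keys/values into `heads` slices of
#' `d/heads` dimensions, runs scaled dot-product attention per head,
#' concatenates and applies the output projection. Shape-preserving.
#'
#' @param tokens `N x d` token matrix.
#' @param cfg [encoder_config()].
#' @param weights One block's weights from [init_encoder()].
#' @return `N x d` matrix.
#' @export
mhsa <- function(tokens, cfg, weights) {
  if (ncol(tokens) != cfg$d) stop("token dimension does not match config")
  mhsa_apply(ad_const(tokens), weights, cfg, training = FALSE)$val
}

#' Two-layer GELU MLP (evaluation mode)
#'
#' `W2 %*% GELU(W1 x + b1) + b2`, applied row-wise to a token matrix.
#'
#' @param x `N x d` token matrix.
#' @param cfg [encoder_config()].
#' @param weights The `mlp` element of one block's weights.
#' @return `N x d` matrix.
#' @export
mlp_block <- function(x, cfg, weights) {
  mlp_apply(ad_const(x), weights, encoder_config(d = ncol(x), heads = 1L,
                                                 mlp_ratio = ncol(weights$W1) / ncol(x),
                                                 dropout = 0), training = FALSE)$val
}

#' Run the encoder stack (evaluation mode)
#'
#' `n_blocks` repetitions of: layer-norm, multi-head self-attention,
#' layer-norm, residual add, then MLP with residual add. With zero blocks
#' this is the identity. Token count and dimension are preserved.
#'
#' @param tokens `N x d` token matrix.
#' @param cfg [encoder_config()].
#' @param weights [init_encoder()] result.
#' @return `N x d` matrix.
#' @export
encoder_stack <- function(tokens, cfg, weights) {
  grid <- attr(tokens, "grid")
  out <- encoder_apply(ad_const(unclass(tokens)), weights, cfg, training = FALSE)$val
  attr(out, "grid") <- grid
  out
}

#' Flatten a token sequence row-major
#'
#' `N x D` tokens become a length `N*D` vector (token 1's features first);
#' `matrix(v, N, D, byrow = TRUE)` inverts it exactly.
#'
#' @param tokens Token matrix.
#' @return Numeric vector of length `N * D`.
#' @export
flatten_tokens <- function(tokens) as.vector(t(unclass(tokens)))
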