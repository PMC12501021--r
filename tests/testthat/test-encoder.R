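# Attention, layer normalization, MLP and the encoder stack.

test_that("scaled dot-product attention matches hand-computed oracles", {
  # N = 1: softmax over one key is 1, output is V
  V1 <- matrix(c(3, -2), 1, 2)
  expect_equal(scaled_dot_attention(matrix(1, 1, 1), matrix(5, 1, 1), V1), V1)
  # identical key rows: uniform weights, output is the column mean of V
  Q <- matrix(rnorm(6), 3, 2); K <- matrix(rep(c(1, 2), each = 3), 3, 2)
  V <- matrix(rnorm(9), 3, 3)
  out <- scaled_dot_attention(Q, K, V, return_weights = TRUE)
  expect_equal(attr(out, "weights"), matrix(1 / 3, 3, 3))
  expect_equal(out[1, ], colMeans(V), ignore_attr = TRUE)
  # brute-force 2x2 case, d_k = 1
  Q2 <- matrix(c(1, 0), 2, 1); V2 <- matrix(c(1, 0), 2, 1)
  s <- Q2 %*% t(Q2) / 1
  A <- exp(s) / rowSums(exp(s))
  expect_equal(scaled_dot_attention(Q2, Q2, V2), A %*% V2)
  expect_error(scaled_dot_attention(matrix(1, 2, 0), matrix(1, 2, 0), V2), "d_k")
})

test_that("attention rows are stochastic across heads and blocks", {
  ns <- asNamespace("dermofusion")
  cfg <- encoder_config(n_blocks = 2L, heads = 4L, d = 16L, dropout = 0)
  w <- init_encoder(cfg, seed = 9)
  set.seed(1)
  x <- matrix(rnorm(10 * 16), 10, 16)
  # tap every head's weights in every block
  for (b in 1:2) {
    p <- w[[b]]
    xa <- layer_norm(x, cfg$eps)
    Q <- sweep(xa %*% p$Wq, 2, p$bq, "+")
    K <- sweep(xa %*% p$Wk, 2, p$bk, "+")
    V <- sweep(xa %*% p$Wv, 2, p$bv, "+")
    for (h in 1:4) {
      cols <- ((h - 1) * 4 + 1):(h * 4)
      o <- scaled_dot_attention(Q[, cols], K[, cols], V[, cols], return_weights = TRUE)
      A <- attr(o, "weights")
      expect_true(all(A >= 0))
      expect_equal(rowSums(A), rep(1, 10), tolerance = 1e-6)
    }
    x <- encoder_stack(x, encoder_config(n_blocks = 1L, heads = 4L, d = 16L, dropout = 0),
                       w[b])
  }
})

test_that("layer normalization matches its closed form", {
  expect_equal(layer_norm(c(5, 5, 5, 5)), rep(0, 4), tolerance = 1e-3)
  expect_equal(layer_norm(c(1, 3), eps = 1e-12), c(-1, 1), tolerance = 1e-6)
  set.seed(4)
  x <- matrix(rnorm(5 * 8, 10, 3), 5, 8)
  y <- layer_norm(x)
  expect_equal(rowMeans(y), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 5), tolerance = 1e-5)
  expect_error(layer_norm(x, eps = 0), "eps")
})

test_that("the MLP block computes W2 GELU(W1 x + b1) + b2", {
  cfg <- encoder_config(heads = 1L, d = 4L, mlp_ratio = 2, dropout = 0)
  w <- init_encoder(cfg, seed = 2)[[1]]$mlp
  x <- matrix(rnorm(3 * 4), 3, 4)
  manual <- sweep(gelu(sweep(x %*% w$W1, 2, w$b1, "+")) %*% w$W2, 2, w$b2, "+")
  expect_equal(mlp_block(x, cfg, w), manual, tolerance = 1e-12)
  # zero weights: constant output b2
  w0 <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = c(1, 2, 3, 4))
  expect_equal(mlp_block(x, cfg, w0), matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4))
})

test_that("mhsa is shape-preserving, permutation-equivariant, and reduces to one head", {
  cfg1 <- encoder_config(heads = 1L, d = 8L, dropout = 0)
  w <- init_encoder(cfg1, seed = 12)[[1]]
  set.seed(5)
  x <- matrix(rnorm(6 * 8), 6, 8)
  out <- mhsa(x, cfg1, w)
  expect_equal(dim(out), dim(x))
  # single head: equals scaled_dot_attention plus the output projection
  Q <- sweep(x %*% w$Wq, 2, w$bq, "+")
  K <- sweep(x %*% w$Wk, 2, w$bk, "+")
  V <- sweep(x %*% w$Wv, 2, w$bv, "+")
  manual <- sweep(scaled_dot_attention(Q, K, V) %*% w$Wo, 2, w$bo, "+")
  expect_equal(out, manual, tolerance = 1e-12)
  # permutation equivariance (no positional encoding involved)
  cfg4 <- encoder_config(heads = 4L, d = 8L, dropout = 0)
  w4 <- init_encoder(cfg4, seed = 13)[[1]]
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(mhsa(x[perm, ], cfg4, w4), mhsa(x, cfg4, w4)[perm, ], tolerance = 1e-10)
  expect_error(mhsa(x, encoder_config(heads = 3L, d = 8L), w), "divisible")
})

test_that("the encoder stack is deterministic, shape-preserving, identity at depth 0", {
  cfg <- encoder_config(n_blocks = 3L, heads = 2L, d = 12L, dropout = 0)
  w <- init_encoder(cfg, seed = 3)
  set.seed(6)
  x <- matrix(rnorm(9 * 12), 9, 12)
  expect_identical(encoder_stack(x, encoder_config(n_blocks = 0L, heads = 2L, d = 12L), list()), x)
  o1 <- encoder_stack(x, cfg, w)
  expect_identical(o1, encoder_stack(x, cfg, w))
  expect_equal(dim(o1), c(9L, 12L))
  expect_true(all(is.finite(o1)))
})

test_that("with attention and MLP weights zeroed each block adds only normalized terms", {
  # a = LN(LN(x) attention with zero weights) = LN(bias terms) = 0 vector
  # (zero weights, zero biases -> attention output 0, LN(0) = 0), so the
  # block reduces to x + 0 + MLP(x) with MLP zero -> x unchanged.
  cfg <- encoder_config(n_blocks = 2L, heads = 2L, d = 8L, dropout = 0)
  w <- init_encoder(cfg, seed = 1)
  for (b in seq_along(w)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo")) w[[b]][[nm]][] <- 0
    for (nm in c("W1", "b1", "W2", "b2")) w[[b]]$mlp[[nm]][] <- 0
  }
  set.seed(8)
  x <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(encoder_stack(x, cfg, w), x, tolerance = 1e-12)
})

test_that("token flattening is row-major with an exact inverse", {
  tok <- matrix(1:12, 3, 4, byrow = TRUE) * 1.5
  v <- flatten_tokens(tok)
  expect_equal(length(v), 12L)
  expect_equal(v[1:4], tok[1, ])                      # token 1 first
  expect_equal(matrix(v, 3, 4, byrow = TRUE), tok)    # exact inverse
  expect_equal(flatten_tokens(matrix(7, 1, 1)), 7)
  # the full-geometry arithmetic: 300 tokens x 256 dims
  expect_equal(300L * 256L, 76800L)
})
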