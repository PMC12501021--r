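# Minimal reverse-mode automatic differentiation over matrices.
#
# Nodes are environments holding a value, an accumulated gradient, parent
# nodes and a backward closure. Graphs are built eagerly during a forward
# pass and differentiated by a reverse topological sweep. This core is
# deliberately small: just the operations the model needs (matmul, bias
# add, ReLU/GELU, row softmax, row layer-norm, column batch-norm, gather
# for im2col convolution, pooling, dropout, cross-entropy).

the <- new.env(parent = emptyenv())
the$nid <- 0L
the$im2col <- new.env(parent = emptyenv())

new_node <- function(val, parents = list(), backfn = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  the$nid <- the$nid + 1L
  e$nid <- the$nid
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$param <- param
  class(e) <- "ad_node"
  e
}

#' Create an autodiff constant/parameter node
#'
#' Part of the package's small reverse-mode automatic-differentiation
#' core used by the neural components. `ad_const` wraps a value that
#' requires no gradient; `ad_param` marks a trainable parameter.
#'
#' @param val Numeric matrix, vector or scalar.
#' @return An `ad_node` environment with fields `val` and (after
#'   [ad_backward()]) `grad`.
#' @export
ad_const <- function(val) new_node(val)

#' @rdname ad_const
#' @export
ad_param <- function(val) new_node(val, param = TRUE)

as_node <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

#' Reverse-mode backward sweep
#'
#' Seeds the root gradient with ones and accumulates gradients into every
#' reachable node (including parameters) in reverse topological order.
#'
#' @param root Output `ad_node` (typically a scalar loss).
#' @return Invisibly, the root.
#' @export
ad_backward <- function(root) {
  topo <- vector("list", 1024L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  visit <- function(n) {
    key <- as.character(n$nid)
    if (!is.null(visited[[key]])) return(invisible())
    assign(key, TRUE, envir = visited)
    for (p in n$parents) visit(p)
    n_topo <<- n_topo + 1L
    if (n_topo > length(topo)) topo[[2L * n_topo]] <<- NULL
    topo[[n_topo]] <<- n
  }
  visit(root)
  root$grad <- array(1, dim = if (is.null(dim(root$val))) length(root$val) else dim(root$val))
  if (is.null(dim(root$val))) root$grad <- as.numeric(root$grad)
  for (i in seq(n_topo, 1L)) {
    n <- topo[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- arithmetic ----

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$val; bv <- b$val
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  a <- as_node(a)
  new_node(a$val * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$val; bv <- b$val
  new_node(av %*% bv, list(a, b),
           function(g) list(g %*% t(bv), crossprod(av, g)))
}

# X (n x d) + row-broadcast bias (length d)
ad_bias <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(sweep(a$val, 2, b$val, "+"), list(a, b),
           function(g) list(g, colSums(g)))
}

ad_sum <- function(a) {
  a <- as_node(a)
  d <- dim(a$val)
  new_node(sum(a$val), list(a), function(g) list(array(as.numeric(g), d)))
}

ad_mean <- function(a) {
  a <- as_node(a)
  d <- dim(a$val); n <- length(a$val)
  new_node(mean(a$val), list(a), function(g) list(array(as.numeric(g) / n, d)))
}

ad_colmeans <- function(a) {
  a <- as_node(a)
  n <- nrow(a$val); m <- ncol(a$val)
  new_node(matrix(colMeans(a$val), 1, m), list(a),
           function(g) list(matrix(rep(as.numeric(g) / n, each = n), n, m)))
}

# ---- activations / normalizations ----

ad_relu <- function(a) {
  a <- as_node(a)
  mask <- a$val > 0
  new_node(a$val * mask, list(a), function(g) list(g * mask))
}

#' Exact GELU activation
#'
#' `gelu(x) = x * pnorm(x)` - the Gaussian-CDF formulation.
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
gelu <- function(x) x * stats::pnorm(x)

ad_gelu <- function(a) {
  a <- as_node(a)
  x <- a$val
  new_node(gelu(x), list(a),
           function(g) list(g * (stats::pnorm(x) + x * stats::dnorm(x))))
}

ad_softmax_rows <- function(a) {
  a <- as_node(a)
  x <- a$val
  m <- apply(x, 1, max)
  e <- exp(x - m)
  y <- e / rowSums(e)
  new_node(y, list(a), function(g) list((g - rowSums(g * y)) * y))
}

# Row-wise layer normalization without learned affine: per row,
# (x - mean) / sqrt(var + eps) with population variance over the features.
ad_layernorm_rows <- function(a, eps = 1e-6) {
  a <- as_node(a)
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  y <- xc / sd
  new_node(y, list(a), function(g) {
    list((g - rowMeans(g) - y * rowMeans(g * y)) / sd)
  })
}

# Column-wise (per-channel) normalization with learned gain/shift. With a
# single image per forward pass the statistics are those of the current
# feature map (instance normalization); the same computation is used in
# train and eval mode, so evaluation is deterministic.
ad_batchnorm_cols <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_node(a); gamma <- as_node(gamma); beta <- as_node(beta)
  x <- a$val
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd <- sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, sd, "/")
  gv <- as.numeric(gamma$val)
  out <- sweep(sweep(xhat, 2, gv, "*"), 2, as.numeric(beta$val), "+")
  new_node(out, list(a, gamma, beta), function(g) {
    # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat)) / sd, per column
    dxhat <- sweep(g, 2, gv, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"), 2, sd, "/")
    list(dx, colSums(g * xhat), colSums(g))
  })
}

ad_dropout <- function(a, p, training) {
  a <- as_node(a)
  if (!training || p <= 0) return(a)
  d <- dim(a$val)
  mask <- array(stats::rbinom(length(a$val), 1, 1 - p) / (1 - p), d)
  new_node(a$val * mask, list(a), function(g) list(g * mask))
}

# ---- structural ops ----

# Gather with implicit zero at index 0: out[k] = c(0, vec(x))[idx[k] + 1].
# The backward pass scatters gradients back by index (zero slots dropped).
ad_gather_zero <- function(a, idx, out_dim) {
  a <- as_node(a)
  xlen <- length(a$val); xd <- dim(a$val)
  v <- c(0, as.vector(a$val))[idx + 1L]
  dim(v) <- out_dim
  new_node(v, list(a), function(g) {
    gv <- as.vector(g)
    keep <- idx > 0L
    acc <- rowsum(gv[keep], idx[keep])
    out <- numeric(xlen)
    out[as.integer(rownames(acc))] <- acc
    if (!is.null(xd)) dim(out) <- xd
    list(out)
  })
}

ad_slice_cols <- function(a, cols) {
  a <- as_node(a)
  d <- dim(a$val)
  new_node(a$val[, cols, drop = FALSE], list(a), function(g) {
    out <- matrix(0, d[1], d[2])
    out[, cols] <- g
    list(out)
  })
}

ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  widths <- vapply(nodes, function(n) ncol(n$val), 0L)
  ends <- cumsum(widths); starts <- ends - widths + 1L
  new_node(do.call(cbind, lapply(nodes, function(n) n$val)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_transpose <- function(a) {
  a <- as_node(a)
  new_node(t(a$val), list(a), function(g) list(t(g)))
}

# Row-major flatten of an n x d matrix to a 1 x (n*d) row vector.
ad_flatten_rows <- function(a) {
  a <- as_node(a)
  n <- nrow(a$val); d <- ncol(a$val)
  new_node(matrix(as.vector(t(a$val)), 1), list(a),
           function(g) list(matrix(as.vector(g), n, d, byrow = TRUE)))
}

# ---- losses ----

# Mean cross-entropy of rows of logits (B x K) against integer labels
# (1..K). Numerically stable log-sum-exp formulation.
ad_cross_entropy <- function(logits, y) {
  logits <- as_node(logits)
  x <- logits$val
  B <- nrow(x); K <- ncol(x)
  m <- apply(x, 1, max)
  lse <- m + log(rowSums(exp(x - m)))
  loss <- mean(lse - x[cbind(seq_len(B), y)])
  sm <- exp(x - lse)
  new_node(loss, list(logits), function(g) {
    d <- sm
    d[cbind(seq_len(B), y)] <- d[cbind(seq_len(B), y)] - 1
    list(as.numeric(g) * d / B)
  })
}

# ---- parameter-tree helpers ----

# Recursively wrap numeric leaves of a nested list as parameter nodes.
wrap_params <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) lapply(p, wrap_params) else ad_param(p)
}

# Extract values / grads back out of a wrapped tree.
unwrap_values <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p) && !inherits(p, "ad_node")) lapply(p, unwrap_values) else p$val
}

unwrap_grads <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p) && !inherits(p, "ad_node")) return(lapply(p, unwrap_grads))
  if (is.null(p$grad)) array(0, dim = if (is.null(dim(p$val))) length(p$val) else dim(p$val)) else p$grad
}

# Flat numeric view of a parameter tree (used by the parameter counter
# and the finite-gradient checks).
flatten_param_tree <- function(p) {
  if (is.list(p)) unlist(lapply(p, flatten_param_tree), use.names = FALSE) else as.numeric(p)
}

# ---- Adam optimizer over parameter trees ----

adam_init <- function(params) {
  zeros <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) lapply(p, zeros)
    else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      r <- Map(upd, p, g, m, v)
      return(list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
                  v = lapply(r, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    out <- p - lr * as.vector(mh / (sqrt(vh) + eps))
    list(p = out, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
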