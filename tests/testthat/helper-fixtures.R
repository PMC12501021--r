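# Shared fixtures, built in code. Heavier objects are memoized so the
# suite constructs them once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, expr, envir = .fixtures)
  .fixtures[[key]]
}

# 3x3 impulse image used for the hand-worked filter examples
impulse3 <- function() matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3)

tiny_hybrid <- function() memo("tiny_hybrid", build_hybrid(hybrid_config("tiny"), seed = 5))

tiny_dataset <- function(n = 3) memo(paste0("ds", n),
  generate_dataset(n, size = c(70, 70), seed = 3))

random_rgb <- function(h = 24, w = 24, seed = 99) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}

# Brute-force local variance of a w x w reflect-padded window, used as an
# independent oracle against the vectorized implementation.
brute_local_var <- function(m, w) {
  p <- (w - 1) / 2
  h <- nrow(m); wd <- ncol(m)
  ri <- c(p:1, 1:h, h:(h - p + 1)); ci <- c(p:1, 1:wd, wd:(wd - p + 1))
  mp <- m[ri, ci]
  out <- matrix(0, h, wd)
  for (i in 1:h) for (j in 1:wd) {
    win <- mp[i:(i + w - 1), j:(j + w - 1)]
    out[i, j] <- mean(win^2) - mean(win)^2
  }
  out
}

# Confusion matrices reconstructed from published per-class correct/total
# narrative counts: diagonal = correct, the remaining row mass lumped into
# one off-diagonal cell (recall-style metrics depend only on row sums).
cm_from_counts <- function(correct, total, labels = lesion_classes) {
  k <- length(correct)
  cm <- diag(correct)
  for (i in seq_len(k)) {
    wrong <- total[i] - correct[i]
    j <- if (i == k) 1L else i + 1L
    cm[i, j] <- cm[i, j] + wrong
  }
  dimnames(cm) <- list(true = labels, pred = labels)
  cm
}

# Printed per-class counts (order AKIEC, BCC, BKL, DF, MEL, NV, VASC)
hybrid_counts <- function() list(
  correct = c(57, 95, 203, 20, 209, 1337, 23),
  total   = c(65, 103, 220, 23, 223, 1341, 28))

vit_counts <- function() list(
  correct = c(34, 89, 207, 7, 203, 1317, 9),
  total   = c(65, 103, 220, 23, 224, 1341, 28))

densenet_nv_counts <- function() list(correct = 1301, total = 1341)

# Published per-class metric columns used for macro-aggregation checks
densenet_table3 <- function() list(
  auc         = c(61.5, 68.9, 94.2, 71.5, 83.5, 91.8, 60.8),
  precision   = c(60, 67, 93.8, 70.6, 81.1, 93.7, 58.8),
  accuracy    = c(32.3, 70.9, 95.9, 52.2, 76.8, 97, 35.7),
  sensitivity = c(32.5, 71.5, 95.8, 52.6, 77.4, 97.7, 36.5),
  specificity = c(99.2, 98.5, 99.1, 99.5, 98.3, 86.9, 99.7))

hybrid_table5 <- function() list(
  sensitivity = c(88.2, 92.5, 92.4, 86.9, 93.8, 99.5, 82.3),
  precision   = c(90.5, 92.2, 96.2, 90.9, 93.7, 98.5, 95.8))

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
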