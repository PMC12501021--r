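# Declarative DenseNet169 builder: an architecture table of stages (conv,
# pool, dense blocks, transitions, removed) from which both the original
# and the pruned variant are constructed, with exact parameter accounting.
#
# Reconstruction conventions (the stage table states layer counts only):
# growth rate 32, pre-activation BN-ReLU-Conv ordering, 1x1 bottlenecks of
# width 4 x growth before every 3x3 conv, transition compression 0.5, and
# global average pooling after the final stage.

#' Architecture table for the DenseNet169 backbone
#'
#' The `"original"` variant is the standard DenseNet169 stage list
#' (7x7/64 stem, dense blocks of 6/12/32/32 conv layers); the
#' `"enhanced"` variant prunes it: a 3x3/32 stem, dense block 3 halved to
#' 16 conv layers, and dense block 4 removed entirely.
#'
#' @param variant `"enhanced"` (pruned) or `"original"`.
#' @param input_size Input image side in pixels (square), default 224.
#' @param growth Dense-block growth rate (filters added per conv layer).
#' @param compression Transition-layer channel compression factor.
#' @return A data.frame of class `architecture_table` with one row per
#'   stage and attributes `variant`, `growth`, `compression`.
#' @export
densenet_table <- function(variant = c("enhanced", "original"),
                           input_size = 224L, growth = 32L, compression = 0.5) {
  variant <- match.arg(variant)
  row <- function(name, kind, kernel = NA, filters = NA, stride = NA, repeats = NA)
    data.frame(name = name, kind = kind, kernel = kernel, filters = filters,
               stride = stride, repeats = repeats, stringsAsFactors = FALSE)
  stem <- if (variant == "enhanced") row("initial_conv", "conv", 3, 32, 2)
          else row("initial_conv", "conv", 7, 64, 2)
  db3 <- if (variant == "enhanced") row("dense_block_3", "dense_block", 3, growth, 1, 16)
         else row("dense_block_3", "dense_block", 3, growth, 1, 32)
  db4 <- if (variant == "enhanced") row("dense_block_4", "removed")
         else row("dense_block_4", "dense_block", 3, growth, 1, 32)
  tab <- rbind(
    row("input", "input", filters = 3, stride = input_size),
    stem,
    row("pool", "pool", 3, NA, 2),
    row("dense_block_1", "dense_block", 3, growth, 1, 6),
    row("transition_1", "transition", 1, NA, 1),
    row("dense_block_2", "dense_block", 3, growth, 1, 12),
    row("transition_2", "transition", 1, NA, 1),
    db3,
    row("transition_3", "transition", 1, NA, 1),
    db4)
  structure(tab, variant = variant, growth = growth, compression = compression,
            class = c("architecture_table", "data.frame"))
}

#' Build a backbone model from an architecture table
#'
#' Initializes every stage's weights (He-normal convolutions without
#' biases, batch-norm gain/shift) and records the spatial/channel
#' geometry of each stage. Within a dense block, conv layer l receives
#' the concatenation of the block input and all l-1 previous layer
#' outputs, so its input channel count is `block_in + (l-1) * growth`.
#' The network output is the global-average-pooled feature vector of the
#' final retained stage (a trailing BN-ReLU is added when the last stage
#' is a dense block, per the pre-activation convention).
#'
#' @param table [densenet_table()] or a compatible stage table.
#' @param seed Weight-initialization seed.
#' @return A `backbone_model` list: `table`, `params`, `geom` (per-stage
#'   H, W, channels), `out_dim`, `input_size`.
#' @export
build_backbone <- function(table, seed = 1L) {
  growth <- attr(table, "growth") %||% 32L
  compression <- attr(table, "compression") %||% 0.5
  with_local_seed(seed, {
    params <- list()
    geom <- list()
    H <- W <- NULL; C <- NULL
    input_size <- NA_integer_
    for (i in seq_len(nrow(table))) {
      st <- table[i, ]
      p <- NULL
      switch(st$kind,
        input = {
          input_size <- as.integer(st$stride)
          H <- W <- input_size; C <- as.integer(st$filters)
        },
        conv = {
          p <- list(conv = conv_init(st$kernel, C, st$filters),
                    bn = bn_init(st$filters))
          k <- st$kernel; s <- st$stride
          H <- (H + 2L * ((k - 1L) %/% 2L) - k) %/% s + 1L
          W <- (W + 2L * ((k - 1L) %/% 2L) - k) %/% s + 1L
          C <- as.integer(st$filters)
        },
        pool = {
          k <- st$kernel; s <- st$stride
          H <- (H + 2L * ((k - 1L) %/% 2L) - k) %/% s + 1L
          W <- (W + 2L * ((k - 1L) %/% 2L) - k) %/% s + 1L
        },
        dense_block = {
          bneck <- 4L * growth
          layers <- list()
          cin <- C
          for (l in seq_len(st$repeats)) {
            layers[[l]] <- list(
              bn1 = bn_init(cin), conv1 = conv_init(1L, cin, bneck),
              bn2 = bn_init(bneck), conv2 = conv_init(3L, bneck, growth))
            cin <- cin + growth
          }
          p <- layers
          C <- cin
        },
        transition = {
          cout <- as.integer(floor(C * compression))
          p <- list(bn = bn_init(C), conv = conv_init(1L, C, cout))
          C <- cout
          H <- H %/% 2L; W <- W %/% 2L
        },
        removed = NULL,
        stop("unknown stage kind: ", st$kind))
      params[[st$name]] <- p
      geom[[st$name]] <- list(H = H, W = W, C = C)
    }
    if (table$kind[nrow(table)] == "dense_block")
      params[["final_bn"]] <- list(bn = bn_init(C))
    structure(list(table = table, params = params, geom = geom,
                   out_dim = C, input_size = input_size),
              class = "backbone_model")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Graph-building forward pass over a (H*W) x 3 input node; params may be
# the model's numeric tree or a wrapped ad-node tree (for training).
backbone_apply <- function(model, x, params = model$params) {
  table <- model$table
  growth <- attr(table, "growth") %||% 32L
  H <- W <- model$input_size; C <- 3L
  for (i in seq_len(nrow(table))) {
    st <- table[i, ]
    p <- params[[st$name]]
    if (st$kind == "input" || st$kind == "removed") next
    if (st$kind == "conv") {
      r <- conv_apply(x, p$conv, H, W, C, st$kernel, st$stride)
      x <- ad_relu(ad_batchnorm_cols(r$x, p$bn$gamma, p$bn$beta))
      H <- r$H; W <- r$W; C <- as.integer(st$filters)
    } else if (st$kind == "pool") {
      r <- ad_maxpool(x, H, W, C, st$kernel, st$stride)
      x <- r$x; H <- r$H; W <- r$W
    } else if (st$kind == "dense_block") {
      for (l in seq_len(st$repeats)) {
        pl <- p[[l]]
        h <- ad_relu(ad_batchnorm_cols(x, pl$bn1$gamma, pl$bn1$beta))
        h <- conv_apply(h, pl$conv1, H, W, C, 1L)$x
        h <- ad_relu(ad_batchnorm_cols(h, pl$bn2$gamma, pl$bn2$beta))
        h <- conv_apply(h, pl$conv2, H, W, 4L * growth, 3L)$x
        x <- ad_cbind(list(x, h))
        C <- C + growth
      }
    } else if (st$kind == "transition") {
      h <- ad_relu(ad_batchnorm_cols(x, p$bn$gamma, p$bn$beta))
      h <- conv_apply(h, p$conv, H, W, C, 1L)$x
      C <- ncol(if (inherits(p$conv$W, "ad_node")) p$conv$W$val else p$conv$W)
      r <- ad_avgpool(h, H, W, C)
      x <- r$x; H <- r$H; W <- r$W
    }
  }
  if (!is.null(params[["final_bn"]])) {
    fb <- params[["final_bn"]]
    x <- ad_relu(ad_batchnorm_cols(x, fb$bn$gamma, fb$bn$beta))
  }
  ad_colmeans(x)  # global average pooling -> 1 x C
}

#' Count trainable parameters of a model
#'
#' Exact count over every weight matrix and batch-norm gain/shift in the
#' model's parameter tree.
#'
#' @param model A `backbone_model` (or any object with a `params` tree,
#'   e.g. a `hybrid_model`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  length(flatten_param_tree(p))
}

#' Backbone forward pass
#'
#' Deterministic evaluation: intensities are scaled to \[0, 1\] and pushed
#' through the stage list; the result is the global-average-pooled
#' feature vector after the final retained stage.
#'
#' @param model [build_backbone()] result.
#' @param img Raster image of exactly `input_size x input_size x 3`.
#' @return Numeric feature vector of length `model$out_dim`.
#' @export
backbone_forward <- function(model, img) {
  img <- as_raster(img)
  d <- dim(img)
  if (length(d) != 3L || d[1] != model$input_size || d[2] != model$input_size)
    stop("backbone expects a ", model$input_size, "x", model$input_size, "x3 image")
  x <- ad_const(map_to_mat(img / 255))
  as.numeric(backbone_apply(model, x)$val)
}

#' Dense-connectivity channel arithmetic
#'
#' Input channel count of conv layer `l` of a dense block:
#' `block_in + (l - 1) * growth`.
#'
#' @param block_in Channels entering the block.
#' @param l Layer index (1-based).
#' @param growth Growth rate.
#' @return Integer channel count.
#' @export
dense_layer_channels <- function(block_in, l, growth = 32L)
  as.integer(block_in + (l - 1L) * growth)
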