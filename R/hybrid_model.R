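# Full hybrid model: patch embedding -> SDEB -> transformer encoder ->
# flatten, in parallel with the pruned DenseNet backbone; element-wise
# feature fusion after per-branch linear projection to a common dimension
# (the two flattened vectors differ in length, so direct element-wise
# addition needs the alignment); then the normalization/dropout/MLP
# classifier head with softmax. Includes a desk-scale training harness.

#' Fusion / classifier-head configuration
#'
#' @param dim Common fusion dimension both branch vectors are projected
#'   to (default 1024).
#' @param hidden Hidden width of the classifier head MLP.
#' @param dropout Head dropout probability.
#' @param n_classes Number of classes (7).
#' @return List of class `fusion_config`.
#' @export
fusion_config <- function(dim = 1024L, hidden = 256L, dropout = 0.1,
                          n_classes = 7L) {
  stopifnot(dim >= 1, hidden >= 1, dropout >= 0, dropout < 1, n_classes >= 2)
  structure(list(dim = as.integer(dim), hidden = as.integer(hidden),
                 dropout = dropout, n_classes = as.integer(n_classes)),
            class = "fusion_config")
}

#' Hybrid model configuration
#'
#' Two presets: `"full"` uses the full working geometry (600 x 450
#' transformer branch cut into 30 x 30 patches -> 300 tokens of dimension
#' 256, six 8-head encoder blocks, the pruned DenseNet169 at 224 x 224,
#' fusion dimension 1024) and `"tiny"` a desk-scale geometry for
#' training-loop work (70 x 70 / patch 10 -> 7 x 7 token grid, two
#' 2-head blocks of dimension 16, a miniature backbone).
#'
#' @param preset `"tiny"` (desk-scale) or `"full"`.
#' @return List of class `hybrid_config` with elements `vit_size`,
#'   `patch`, `pe_base`, `encoder`, `sdeb`, `backbone_table`, `fusion`.
#' @export
hybrid_config <- function(preset = c("tiny", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    cfg <- list(
      vit_size = c(450L, 600L), patch = 30L, pe_base = 1000,
      encoder = encoder_config(n_blocks = 6L, heads = 8L, d = 256L),
      sdeb = sdeb_config(),
      backbone_table = densenet_table("enhanced"),
      fusion = fusion_config(dim = 1024L))
  } else {
    tiny_table <- densenet_table("enhanced", input_size = 32L, growth = 8L)
    tiny_table <- tiny_table[tiny_table$name %in%
      c("input", "initial_conv", "pool", "dense_block_1", "transition_1"), ]
    tiny_table$filters[tiny_table$name == "initial_conv"] <- 8L
    tiny_table$repeats[tiny_table$name == "dense_block_1"] <- 2L
    attr(tiny_table, "growth") <- 8L; attr(tiny_table, "compression") <- 0.5
    class(tiny_table) <- c("architecture_table", "data.frame")
    cfg <- list(
      vit_size = c(70L, 70L), patch = 10L, pe_base = 1000,
      encoder = encoder_config(n_blocks = 2L, heads = 2L, d = 16L,
                               mlp_ratio = 2, dropout = 0),
      sdeb = sdeb_config(branches = list(c(3, 8), c(5, 8), c(7, 16)),
                         channels = 16L),
      backbone_table = tiny_table,
      fusion = fusion_config(dim = 32L, hidden = 32L, dropout = 0))
  }
  cfg$preset <- preset
  structure(cfg, class = "hybrid_config")
}

#' Build the hybrid model
#'
#' Initializes every component's weights from a single seed: the patch
#' projection, SDEB, encoder, backbone, the two fusion projections and
#' the classifier head. The SDEB fused channel count must equal the
#' encoder dimension (its output tokens feed the encoder directly).
#'
#' @param cfg [hybrid_config()].
#' @param seed Integer seed.
#' @return A `hybrid_model` list with `cfg`, `params`, `backbone` and
#'   derived geometry (`grid`, `n_tokens`, `pe`).
#' @export
build_hybrid <- function(cfg = hybrid_config("tiny"), seed = 1L) {
  stopifnot(inherits(cfg, "hybrid_config"))
  d <- cfg$encoder$d
  if (cfg$sdeb$channels != d)
    stop("SDEB fused channels must equal the encoder dimension")
  H <- cfg$vit_size[1]; W <- cfg$vit_size[2]; P <- cfg$patch
  n_tok <- num_patches(H, W, P)
  grid <- c(rows = H %/% P, cols = W %/% P)
  backbone <- build_backbone(cfg$backbone_table, seed = seed + 1L)
  with_local_seed(seed, {
    params <- list(
      patch_proj = list(W = matrix(rnorm(P * P * 3 * d, 0, sqrt(1 / (P * P * 3))),
                                   P * P * 3, d), b = numeric(d)),
      sdeb = init_sdeb(cfg$sdeb, d, seed = seed + 2L),
      encoder = init_encoder(cfg$encoder, seed = seed + 3L),
      backbone = backbone$params,
      fuse = list(vit = dense_init(n_tok * d, cfg$fusion$dim),
                  dense = dense_init(backbone$out_dim, cfg$fusion$dim)),
      head = list(fc1 = dense_init(cfg$fusion$dim, cfg$fusion$hidden),
                  fc2 = dense_init(cfg$fusion$hidden, cfg$fusion$n_classes)))
    structure(list(cfg = cfg, params = params, backbone = backbone,
                   grid = grid, n_tokens = n_tok,
                   pe = sinusoidal_pe(n_tok, d, cfg$pe_base)),
              class = "hybrid_model")
  })
}

#' Element-wise feature fusion
#'
#' Projects the transformer-branch and CNN-branch feature vectors to the
#' common fusion dimension and adds them element-wise.
#'
#' @param f_vit,f_dense Numeric feature vectors.
#' @param weights List with `vit` and `dense` dense-layer weights; pass
#'   `NULL` for identity projections (the vectors must then already share
#'   a length).
#' @return Fused numeric vector.
#' @export
fuse_features <- function(f_vit, f_dense, weights = NULL) {
  if (is.null(weights)) {
    if (length(f_vit) != length(f_dense))
      stop("identity fusion requires equal feature lengths")
    return(f_vit + f_dense)
  }
  a <- as.numeric(matrix(f_vit, 1) %*% weights$vit$W + weights$vit$b)
  b <- as.numeric(matrix(f_dense, 1) %*% weights$dense$W + weights$dense$b)
  if (length(a) != length(b)) stop("projected dims mismatch")
  a + b
}

head_apply <- function(fused, head, dropout, training = FALSE, eps = 1e-6) {
  x <- ad_layernorm_rows(fused, eps)    # LN over the fused features
  x <- ad_dropout(x, dropout, training)
  x <- dense_apply(x, head$fc1)
  x <- ad_dropout(x, dropout, training)
  dense_apply(x, head$fc2)              # logits
}

#' Softmax over class scores
#' @param z Numeric vector of scores.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Classifier head (evaluation mode)
#'
#' Layer-norm, dropout (inactive in eval), dense, dropout, dense to the
#' class scores, then softmax.
#'
#' @param fused Fused feature vector.
#' @param weights Head weights (`fc1`, `fc2`).
#' @return Probability vector over the classes.
#' @export
classify <- function(fused, weights) {
  logits <- head_apply(ad_const(matrix(fused, 1)), weights, dropout = 0,
                       training = FALSE)$val
  softmax(as.numeric(logits))
}

# Resize an image to both branch resolutions and precompute the static
# numeric inputs (patch matrix, backbone feature-map layout) once; the
# result can be fed to hybrid_apply repeatedly (e.g. across epochs).
hybrid_prepare <- function(model, img) {
  cfg <- model$cfg
  img <- as_raster(img)
  vit_img <- resize_image(img, cfg$vit_size[1], cfg$vit_size[2])
  cnn_img <- resize_image(img, model$backbone$input_size, model$backbone$input_size) / 255
  list(patches = patchify(vit_img, cfg$patch)$patches / 255,
       cnn = map_to_mat(cnn_img))
}

# Full forward graph for one image; params defaults to the model's
# numeric tree (inference) or a wrapped node tree (training).
hybrid_apply <- function(model, img, params = model$params, training = FALSE) {
  cfg <- model$cfg
  prep <- if (is.list(img) && !is.null(img$patches)) img else hybrid_prepare(model, img)
  # transformer branch (intensities scaled to [0, 1])
  tok <- ad_bias(ad_matmul(ad_const(prep$patches), params$patch_proj$W), params$patch_proj$b)
  tok <- ad_add(tok, ad_const(model$pe))
  rows <- model$grid[["rows"]]; cols <- model$grid[["cols"]]
  # tokens (row-major) -> column-major map rows for convolution
  perm_rm_to_cm <- order(token_perm(rows, cols))
  xmap <- ad_permute_rows(tok, perm_rm_to_cm)
  xmap <- sdeb_apply(xmap, params$sdeb, cfg$sdeb, rows, cols, cfg$encoder$d)
  tok <- ad_permute_rows(xmap, token_perm(rows, cols))
  tok <- encoder_apply(tok, params$encoder, cfg$encoder, training)
  f_vit <- ad_flatten_rows(tok)                       # 1 x (T*D)
  # CNN branch
  f_dense <- backbone_apply(model$backbone, ad_const(prep$cnn),
                            params = params$backbone)  # 1 x out_dim
  # fusion + head
  fused <- ad_add(dense_apply(f_vit, params$fuse$vit),
                  dense_apply(f_dense, params$fuse$dense))
  head_apply(fused, params$head, cfg$fusion$dropout, training)
}

#' Hybrid forward pass (evaluation mode)
#'
#' Resizes the (already preprocessed) image to both branch resolutions,
#' runs patch embedding, SDEB, the encoder stack and flattening in the
#' transformer branch, the backbone in the CNN branch, fuses and
#' classifies. Deterministic for fixed weights.
#'
#' @param img RGB raster image.
#' @param model [build_hybrid()] result.
#' @return Named probability vector over [lesion_classes], summing to 1.
#' @export
hybrid_forward <- function(img, model) {
  logits <- hybrid_apply(model, as_raster(img), training = FALSE)$val
  setNames(softmax(as.numeric(logits)),
           lesion_classes[seq_len(model$cfg$fusion$n_classes)])
}

#' Training configuration for the smoke harness
#'
#' @param epochs Training epochs (>= 0).
#' @param lr Adam learning rate.
#' @param batch_size Gradient-accumulation batch size.
#' @param seed RNG seed governing shuffling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 30L, lr = 1e-3, batch_size = 7L, seed = 7L) {
  stopifnot(epochs >= 0L, lr > 0, batch_size >= 1L)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training harness
#'
#' Minimizes categorical cross-entropy with Adam over the full model
#' (every branch receives gradients). With `epochs = 0` the weights are
#' returned bit-identical to initialization. Intended for small synthetic
#' datasets and the tiny preset; it is a correctness harness, not a
#' large-scale trainer.
#'
#' @param dataset List with `images` and integer `labels` 0..K-1.
#' @param model [build_hybrid()] result.
#' @param cfg [train_config()].
#' @param verbose Print per-epoch loss.
#' @return List: trained `model`, `history` (mean loss per epoch),
#'   `train_accuracy` (final-epoch accuracy on the training set).
#' @export
fit_smoke <- function(dataset, model, cfg = train_config(), verbose = FALSE) {
  n <- length(dataset$images)
  if (n == 0L) stop("empty dataset")
  y <- as.integer(dataset$labels) + 1L
  params <- model$params
  history <- numeric(0)
  if (cfg$epochs > 0L) {
    prep <- lapply(dataset$images, function(im) hybrid_prepare(model, im))
    state <- adam_init(params)
    with_local_seed(cfg$seed, {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        for (start in seq(1L, n, by = cfg$batch_size)) {
          ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
          wp <- wrap_params(params)
          loss_node <- NULL
          for (i in ids) {
            logits <- hybrid_apply(model, prep[[i]], params = wp,
                                   training = TRUE)
            li <- ad_cross_entropy(logits, y[i])
            loss_node <- if (is.null(loss_node)) li else ad_add(loss_node, li)
          }
          loss_node <- ad_scale(loss_node, 1 / length(ids))
          ad_backward(loss_node)
          ep_loss <- ep_loss + loss_node$val * length(ids)
          upd <- adam_step(params, unwrap_grads(wp), state, lr = cfg$lr)
          params <- upd$params
          state <- upd$state
        }
        history[ep] <- ep_loss / n
        if (verbose) message(sprintf("epoch %d  loss %.4f", ep, history[ep]))
      }
    })
  }
  model$params <- params
  preds <- vapply(dataset$images, function(im)
    which.max(hybrid_forward(im, model)) - 1L, 0L)
  list(model = model, history = history,
       train_accuracy = mean(preds == dataset$labels))
}

#' Predict class probabilities for a list of images
#' @param model Trained `hybrid_model`.
#' @param images List of RGB rasters.
#' @return Matrix (n x K) of probabilities with class-name columns.
#' @export
predict_hybrid <- function(model, images) {
  t(vapply(images, function(im) hybrid_forward(im, model),
           numeric(model$cfg$fusion$n_classes)))
}
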