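# Residual encoder (ResNet18 layout, single grayscale input channel) and the
# dual-image pair classification head.
#
# A residual block computes f(h(x) + F(x, W)) where F is conv3x3-BN-ReLU-
# conv3x3-BN, h is the identity (or a 1x1 conv + BN projection when channel
# count or resolution changes) and f is ReLU. The encoder is the standard
# 18-layer layout: 7x7/2 stem conv + BN + ReLU + 3x3/2 max pool, four stages
# of two blocks at widths 64/128/256/512 (first block of stages 2-4 strides
# 2 with a projection skip), and global average pooling to a 512-vector.
# One shared encoder processes both drug images; the head concatenates the
# two embeddings (1024), applies FC 1024->1024, ReLU, dropout, FC 1024->2.

new_bn <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C))
}

he_conv <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

he_linear <- function(fin, fout) {
  list(W = matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout),
       b = rep(0, fout))
}

new_residual_block <- function(cin, cout, stride) {
  down <- if (stride != 1L || cin != cout) {
    list(conv = list(W = he_conv(1L, cin, cout)), bn = new_bn(cout))
  } else NULL
  list(conv1 = list(W = he_conv(3L, cin, cout)), bn1 = new_bn(cout),
       conv2 = list(W = he_conv(3L, cout, cout)), bn2 = new_bn(cout),
       down = down, stride = as.integer(stride),
       cin = as.integer(cin), cout = as.integer(cout))
}

# stage widths and strides of the 18-layer layout
.ENCODER_PLAN <- data.frame(
  cin = c(64, 64, 64, 128, 128, 256, 256, 512),
  cout = c(64, 64, 128, 128, 256, 256, 512, 512),
  stride = c(1, 1, 2, 1, 2, 1, 2, 1)
)

#' Construct the residual encoder
#'
#' @param in_channels Input channel count (1: grayscale feature images).
#' @return An `encoder` list: stem conv/BN, 8 residual blocks, embedding
#'   dimension 512. Weights are He-initialised from the current R RNG state;
#'   call `set.seed()` first for reproducibility.
#' @export
new_encoder <- function(in_channels = 1L) {
  blocks <- lapply(seq_len(nrow(.ENCODER_PLAN)), function(i) {
    new_residual_block(.ENCODER_PLAN$cin[i], .ENCODER_PLAN$cout[i],
                       .ENCODER_PLAN$stride[i])
  })
  structure(list(stem = list(conv = list(W = he_conv(7L, in_channels, 64L)),
                             bn = new_bn(64L)),
                 blocks = blocks, in_channels = as.integer(in_channels),
                 embedding_dim = 512L),
            class = "encoder")
}

#' Construct the pair classifier (shared encoder + two-logit head)
#'
#' @param dropout_p Dropout probability in the head (default 0.5).
#' @param in_channels Image channel count.
#' @param seed Optional integer; when given, seeds the RNG so initialisation
#'   is reproducible.
#' @return A `pair_classifier` list with `$encoder` and `$head`.
#' @export
new_pair_classifier <- function(dropout_p = 0.5, in_channels = 1L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(encoder = new_encoder(in_channels),
                 head = list(fc1 = he_linear(1024L, 1024L),
                             fc2 = he_linear(1024L, 2L),
                             dropout_p = dropout_p)),
            class = "pair_classifier")
}

ddimage_shape_error <- function(message) {
  structure(class = c("ddimage_shape_error", "ddimage_error",
                      "error", "condition"),
            list(message = message, call = NULL))
}

# -- residual block forward/backward ----------------------------------------

#' Forward pass through one residual block
#'
#' Computes `ReLU(h(x) + F(x, W))` where `F` is the two-convolution branch
#' and `h` is the identity or the 1x1 projection. Exposed mainly for the
#' identity-degeneracy property: with the branch parameters all zero and an
#' identity skip, the block reproduces `ReLU(x)` exactly.
#'
#' @param X Activation matrix, `(H*W*N) x cin` channels-last layout.
#' @param block A residual block (element of `encoder$blocks`).
#' @param H,W,N Spatial side(s) and batch size of `X`.
#' @param training Logical; batch-norm mode.
#' @return List with `out`, updated `block` (BN running stats), `H`, `W`
#'   (output sides) and `cache` for the backward pass.
#' @export
residual_block_forward <- function(X, block, H, W, N, training = FALSE) {
  if (ncol(X) != block$cin) {
    stop(ddimage_shape_error(sprintf(
      "residual block expects %d input channels, got %d", block$cin, ncol(X))))
  }
  g1 <- conv_geom(H, W, N, 3L, block$stride, 1L)
  c1 <- conv_fwd(X, g1, block$conv1$W)
  b1 <- bn_fwd(c1$out, block$bn1, training)
  block$bn1 <- b1$bn
  r1 <- relu_fwd(b1$out)
  g2 <- conv_geom(g1$Ho, g1$Wo, N, 3L, 1L, 1L)
  c2 <- conv_fwd(r1$out, g2, block$conv2$W)
  b2 <- bn_fwd(c2$out, block$bn2, training)
  block$bn2 <- b2$bn
  if (is.null(block$down)) {
    skip <- X
    dcache <- NULL
  } else {
    gd <- conv_geom(H, W, N, 1L, block$stride, 0L)
    cd <- conv_fwd(X, gd, block$down$conv$W)
    bd <- bn_fwd(cd$out, block$down$bn, training)
    block$down$bn <- bd$bn
    skip <- bd$out
    dcache <- list(conv = cd$cache, bn = bd$cache)
  }
  pre <- b2$out + skip
  r_out <- relu_fwd(pre)
  list(out = r_out$out, block = block, H = g1$Ho, W = g1$Wo,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, down = dcache,
                    r_out = r_out$cache))
}

residual_block_backward <- function(dY, cache, block) {
  dpre <- relu_bwd(dY, cache$r_out)
  b2 <- bn_bwd(dpre, cache$b2, block$bn2)
  c2 <- conv_bwd(b2$dX, cache$c2, block$conv2$W)
  dr1 <- relu_bwd(c2$dX, cache$r1)
  b1 <- bn_bwd(dr1, cache$b1, block$bn1)
  c1 <- conv_bwd(b1$dX, cache$c1, block$conv1$W)
  dX <- c1$dX
  grads <- list(conv1 = list(W = c1$dW),
                bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = list(W = c2$dW),
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  if (is.null(block$down)) {
    dX <- dX + dpre
    grads$down <- NULL
  } else {
    bd <- bn_bwd(dpre, cache$down$bn, block$down$bn)
    cd <- conv_bwd(bd$dX, cache$down$conv, block$down$conv$W)
    dX <- dX + cd$dX
    grads$down <- list(conv = list(W = cd$dW),
                       bn = list(gamma = bd$dgamma, beta = bd$dbeta))
  }
  list(dX = dX, grads = grads)
}

# -- encoder forward/backward ------------------------------------------------

#' Encode a batch of images into 512-dimensional embeddings
#'
#' @param enc An `encoder`.
#' @param X Image batch as a `(side*side*N) x channels` matrix (stack each
#'   image column-major), or a single `side x side` matrix.
#' @param side Image side in pixels (>= 32, so four stride-2 reductions leave
#'   at least one spatial cell).
#' @param N Number of images in the batch.
#' @param training Logical; batch-norm/dropout mode.
#' @param keep_cache Keep layer caches for a backward pass.
#' @return List with `emb` (N x 512), updated `enc`, and `cache`.
#' @export
encoder_forward <- function(enc, X, side, N = 1L, training = FALSE,
                            keep_cache = FALSE) {
  if (is.matrix(X) && ncol(X) == side && nrow(X) == side && N == 1L) {
    X <- matrix(as.vector(X), ncol = 1L)
  }
  if (side < 32L) {
    stop(ddimage_shape_error(sprintf(
      "image side %d too small: the encoder needs side >= 32", side)))
  }
  if (nrow(X) != side * side * N || ncol(X) != enc$in_channels) {
    stop(ddimage_shape_error("input size does not match side/N/channels"))
  }
  caches <- list()
  g_stem <- conv_geom(side, side, N, 7L, 2L, 3L)
  cs <- conv_fwd(X, g_stem, enc$stem$conv$W)
  bs <- bn_fwd(cs$out, enc$stem$bn, training)
  enc$stem$bn <- bs$bn
  rs <- relu_fwd(bs$out)
  g_pool <- conv_geom(g_stem$Ho, g_stem$Wo, N, 3L, 2L, 1L)
  mp <- maxpool_fwd(rs$out, g_pool)
  H <- g_pool$Ho; W <- g_pool$Wo
  if (keep_cache) {
    caches$stem <- list(conv = cs$cache, bn = bs$cache, relu = rs$cache,
                        pool = mp$cache)
  }
  A <- mp$out
  for (i in seq_along(enc$blocks)) {
    bf <- residual_block_forward(A, enc$blocks[[i]], H, W, N, training)
    enc$blocks[[i]] <- bf$block
    A <- bf$out; H <- bf$H; W <- bf$W
    if (keep_cache) caches$blocks[[i]] <- bf$cache
  }
  gp <- gap_fwd(A, H, W, N)
  if (keep_cache) caches$gap <- gp$cache
  list(emb = gp$out, enc = enc, cache = if (keep_cache) caches else NULL)
}

encoder_backward <- function(dE, cache, enc) {
  dA <- gap_bwd(dE, cache$gap)
  grads <- list(blocks = vector("list", length(enc$blocks)))
  for (i in rev(seq_along(enc$blocks))) {
    bb <- residual_block_backward(dA, cache$blocks[[i]], enc$blocks[[i]])
    dA <- bb$dX
    grads$blocks[[i]] <- bb$grads
  }
  dpool <- maxpool_bwd(dA, cache$stem$pool)
  drelu <- relu_bwd(dpool, cache$stem$relu)
  bs <- bn_bwd(drelu, cache$stem$bn, enc$stem$bn)
  cs <- conv_bwd(bs$dX, cache$stem$conv, enc$stem$conv$W)
  grads$stem <- list(conv = list(W = cs$dW),
                     bn = list(gamma = bs$dgamma, beta = bs$dbeta))
  grads
}

# -- pair head ---------------------------------------------------------------

head_forward <- function(head, E_a, E_b, training = FALSE,
                         keep_cache = FALSE) {
  Z <- cbind(E_a, E_b)
  f1 <- linear_fwd(Z, head$fc1$W, head$fc1$b)
  r1 <- relu_fwd(f1$out)
  dp <- dropout_fwd(r1$out, head$dropout_p, training)
  f2 <- linear_fwd(dp$out, head$fc2$W, head$fc2$b)
  list(logits = f2$out,
       cache = if (keep_cache) list(f1 = f1$cache, r1 = r1$cache,
                                    dp = dp$cache, f2 = f2$cache) else NULL)
}

head_backward <- function(dlogits, cache, head) {
  l2 <- linear_bwd(dlogits, cache$f2, head$fc2$W)
  ddp <- dropout_bwd(l2$dX, cache$dp)
  dr1 <- relu_bwd(ddp, cache$r1)
  l1 <- linear_bwd(dr1, cache$f1, head$fc1$W)
  list(dZ = l1$dX,
       grads = list(fc1 = list(W = l1$dW, b = l1$db),
                    fc2 = list(W = l2$dW, b = l2$db)))
}

#' Forward pass of the pair classifier
#'
#' Both images pass through the one shared encoder; the two 512-embeddings
#' are concatenated (1024) and classified by the head into two logits
#' (column 1: non-interaction, column 2: interaction).
#'
#' @param model A `pair_classifier`.
#' @param img_a,img_b Normalized image matrices (`side x side`).
#' @param train_mode Logical; enables batch statistics and dropout.
#' @return Numeric length-2 logit vector.
#' @export
pair_forward <- function(model, img_a, img_b, train_mode = FALSE) {
  side <- nrow(img_a)
  ea <- encoder_forward(model$encoder, img_a, side, 1L, train_mode)
  eb <- encoder_forward(ea$enc, img_b, side, 1L, train_mode)
  hf <- head_forward(model$head, ea$emb, eb$emb, train_mode)
  drop(hf$logits)
}

#' Symmetric interaction probability for a drug pair
#'
#' Averages the softmax interaction probability over both input orders, so
#' `predict_proba(a, b) == predict_proba(b, a)` by construction.
#'
#' @param model A `pair_classifier` (evaluated in eval mode).
#' @param img_a,img_b Normalized image matrices.
#' @return Interaction probability in [0, 1].
#' @export
predict_proba <- function(model, img_a, img_b) {
  p_ab <- softmax_rows(matrix(pair_forward(model, img_a, img_b), 1))[1, 2]
  p_ba <- softmax_rows(matrix(pair_forward(model, img_b, img_a), 1))[1, 2]
  (p_ab + p_ba) / 2
}

# batched symmetric scores: encode unique images once, run the head on both
# orders; the workhorse behind evaluate()/predict
predict_pairs <- function(model, images, pairs) {
  ids <- unique(c(pairs$drug_a, pairs$drug_b))
  missing <- setdiff(ids, names(images))
  if (length(missing) > 0L) {
    stop(ddimage_config_error(paste0("no image for drug id(s): ",
                                     paste(missing, collapse = ", "))))
  }
  side <- nrow(images[[ids[1]]])
  X <- do.call(rbind, lapply(ids, function(id)
    matrix(as.vector(images[[id]]), ncol = 1L)))
  ef <- encoder_forward(model$encoder, X, side, length(ids), training = FALSE)
  E <- ef$emb
  ia <- match(pairs$drug_a, ids)
  ib <- match(pairs$drug_b, ids)
  p_ab <- softmax_rows(head_forward(model$head, E[ia, , drop = FALSE],
                                    E[ib, , drop = FALSE])$logits)[, 2]
  p_ba <- softmax_rows(head_forward(model$head, E[ib, , drop = FALSE],
                                    E[ia, , drop = FALSE])$logits)[, 2]
  (p_ab + p_ba) / 2
}

# -- parameter bookkeeping ---------------------------------------------------

pluck <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

poke <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- poke(x[[path[[1L]]]], path[-1L], value)
  x
}

# list of list-paths to every learnable parameter (BN running stats excluded)
param_paths <- function(model) {
  paths <- list(
    list("encoder", "stem", "conv", "W"),
    list("encoder", "stem", "bn", "gamma"),
    list("encoder", "stem", "bn", "beta")
  )
  for (i in seq_along(model$encoder$blocks)) {
    base <- list("encoder", "blocks", i)
    paths <- c(paths,
      list(c(base, list("conv1", "W")),
           c(base, list("bn1", "gamma")), c(base, list("bn1", "beta")),
           c(base, list("conv2", "W")),
           c(base, list("bn2", "gamma")), c(base, list("bn2", "beta"))))
    if (!is.null(model$encoder$blocks[[i]]$down)) {
      paths <- c(paths,
        list(c(base, list("down", "conv", "W")),
             c(base, list("down", "bn", "gamma")),
             c(base, list("down", "bn", "beta"))))
    }
  }
  c(paths, list(list("head", "fc1", "W"), list("head", "fc1", "b"),
                list("head", "fc2", "W"), list("head", "fc2", "b")))
}

#' Number of learnable parameters
#'
#' Counts every weight in the model (convolutions, batch-norm scale/shift,
#' linear layers); batch-norm running statistics are not parameters.
#'
#' @param model A `pair_classifier` (or pass `list(encoder = enc)` plus
#'   `encoder_only = TRUE` for the encoder alone).
#' @param encoder_only Count only the encoder's parameters.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, encoder_only = FALSE) {
  paths <- param_paths(model)
  if (encoder_only) {
    paths <- Filter(function(p) identical(p[[1L]], "encoder"), paths)
  }
  sum(vapply(paths, function(p) length(pluck(model, p)), 0))
}

#' Zero every residual branch in the encoder
#'
#' Sets the branch convolution weights and batch-norm scale/shift of every
#' residual block to zero, making F(x) identically zero: identity-skip
#' blocks then compute ReLU(x). Used by the identity-degeneracy checks.
#'
#' @param model A `pair_classifier`.
#' @return The modified model.
#' @export
zero_residual_branches <- function(model) {
  for (i in seq_along(model$encoder$blocks)) {
    b <- model$encoder$blocks[[i]]
    b$conv1$W[] <- 0
    b$conv2$W[] <- 0
    b$bn1$gamma[] <- 0; b$bn1$beta[] <- 0
    b$bn2$gamma[] <- 0; b$bn2$beta[] <- 0
    model$encoder$blocks[[i]] <- b
  }
  model
}

# -- checkpointing -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a single archive with the weights, the full run configuration and
#' the seed, plus a JSON sidecar of the configuration for inspection.
#'
#' @param model A `pair_classifier`.
#' @param path Checkpoint file path.
#' @param config Arbitrary configuration list stored alongside the weights.
#' @param seed The seed the run used.
#' @export
save_checkpoint <- function(model, path, config = list(), seed = NULL) {
  saveRDS(list(model = model, config = config, seed = seed,
               format_version = 1L), path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(config, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return List with `model`, `config`, `seed`.
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(ck) || !is.list(ck) || is.null(ck$model) ||
      !inherits(ck$model, "pair_classifier")) {
    stop(ddimage_config_error(sprintf("not a valid checkpoint: %s", path)))
  }
  ck
}
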