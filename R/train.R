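# Dataset splitting, the training loop, evaluation, the feature ablation
# harness and the logistic-regression baseline.
#
# Training economics: drug pairs share drugs, so each minibatch deduplicates
# its drug images — every unique drug is encoded once, the head runs on the
# (cheap) embedding pairs, and embedding gradients are summed per unique
# drug before one encoder backward pass. This is exact (identical gradients
# to the naive two-passes-per-pair layout), it just removes repeated work.

#' Split configuration
#'
#' @param ratios Train/validation/test fractions, default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer driving the shuffle.
#' @export
split_config <- function(ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop(ddimage_config_error(
      "split ratios must be three positive numbers summing to 1"))
  }
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_config")
}

#' Partition a labeled pair table into train/validation/test
#'
#' Validation and test sizes are `round(n * ratio)`; the remainder goes to
#' the training partition. The shuffle is driven solely by `cfg$seed`, so
#' identical inputs and seed give identical partitions.
#'
#' @param pairs A pair data.frame (columns drug_a, drug_b, label).
#' @param cfg A [split_config()].
#' @return List of three data.frames: `train`, `val`, `test` (disjoint, union
#'   is the input).
#' @export
split_dataset <- function(pairs, cfg = split_config()) {
  stopifnot(inherits(cfg, "split_config"), is.data.frame(pairs))
  n <- nrow(pairs)
  if (n < 5L) {
    stop(ddimage_config_error("need at least 5 pairs to split"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  idx <- sample.int(n)
  n_val <- round(n * cfg$ratios[2])
  n_test <- round(n * cfg$ratios[3])
  n_train <- n - n_val - n_test
  list(train = pairs[idx[seq_len(n_train)], , drop = FALSE],
       val = pairs[idx[n_train + seq_len(n_val)], , drop = FALSE],
       test = pairs[idx[n_train + n_val + seq_len(n_test)], , drop = FALSE])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Training configuration
#'
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param learning_rate Step size (default 1e-3).
#' @param epochs Number of passes over the training pairs.
#' @param batch_size Pairs per minibatch.
#' @param dropout_p Head dropout probability.
#' @param seed Integer seed controlling shuffling, initialisation and dropout.
#' @param patience Early-stopping patience on validation loss (epochs).
#' @param momentum SGD momentum (ignored by Adam).
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 1e-3,
                         epochs = 10L, batch_size = 128L, dropout_p = 0.5,
                         seed = 1L, patience = 10L, momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout_p = dropout_p,
                 seed = as.integer(seed), patience = as.integer(patience),
                 momentum = momentum),
            class = "train_config")
}

# -- optimizer ---------------------------------------------------------------

new_optimizer_state <- function(model, cfg) {
  paths <- param_paths(model)
  zeros <- lapply(paths, function(p) {
    x <- pluck(model, p); x[] <- 0; x
  })
  list(paths = paths, m = zeros, v = zeros, t = 0L)
}

optimizer_step <- function(model, grads, state, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    bc1 <- 1 - b1^state$t
    bc2 <- 1 - b2^state$t
    for (i in seq_along(state$paths)) {
      p <- state$paths[[i]]
      g <- pluck(grads, p)
      state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
      state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
      upd <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
      model <- poke(model, p, pluck(model, p) - upd)
    }
  } else {
    for (i in seq_along(state$paths)) {
      p <- state$paths[[i]]
      g <- pluck(grads, p)
      state$m[[i]] <- cfg$momentum * state$m[[i]] + g
      model <- poke(model, p, pluck(model, p) - lr * state$m[[i]])
    }
  }
  list(model = model, state = state)
}

# gradient tree for the head-only paths merged with encoder grads
.merge_grads <- function(enc_grads, head_grads) {
  list(encoder = enc_grads, head = head_grads)
}

# -- one training step on a batch of pairs (deduplicated images) -------------

train_step <- function(model, images, batch_pairs, side, train_mode = TRUE) {
  ids <- unique(c(batch_pairs$drug_a, batch_pairs$drug_b))
  N <- length(ids)
  X <- do.call(rbind, lapply(ids, function(id)
    matrix(as.vector(images[[id]]), ncol = 1L)))
  ef <- encoder_forward(model$encoder, X, side, N, training = train_mode,
                        keep_cache = TRUE)
  model$encoder <- ef$enc
  ia <- match(batch_pairs$drug_a, ids)
  ib <- match(batch_pairs$drug_b, ids)
  hf <- head_forward(model$head, ef$emb[ia, , drop = FALSE],
                     ef$emb[ib, , drop = FALSE], training = train_mode,
                     keep_cache = TRUE)
  ce <- softmax_ce(hf$logits, batch_pairs$label)
  if (!is.finite(ce$loss)) {
    stop(ddimage_config_error(sprintf(
      "non-finite training loss (%g); check learning rate and inputs",
      ce$loss)))
  }
  hb <- head_backward(ce$dlogits, hf$cache, model$head)
  dA <- hb$dZ[, 1:512, drop = FALSE]
  dB <- hb$dZ[, 513:1024, drop = FALSE]
  # sum embedding gradients per unique drug (exact: each drug's embedding
  # feeds every pair that mentions it)
  dE <- rowsum(rbind(dA, dB), group = c(ia, ib), reorder = FALSE)
  dE <- dE[match(seq_len(N), unique(c(ia, ib))), , drop = FALSE]
  enc_grads <- encoder_backward(dE, ef$cache, model$encoder)
  list(model = model, loss = ce$loss,
       grads = .merge_grads(enc_grads, hb$grads))
}

# mean validation loss + symmetric-score metrics, eval mode
validation_pass <- function(model, images, pairs) {
  ids <- unique(c(pairs$drug_a, pairs$drug_b))
  side <- nrow(images[[ids[1]]])
  X <- do.call(rbind, lapply(ids, function(id)
    matrix(as.vector(images[[id]]), ncol = 1L)))
  ef <- encoder_forward(model$encoder, X, side, length(ids), training = FALSE)
  ia <- match(pairs$drug_a, ids)
  ib <- match(pairs$drug_b, ids)
  hf <- head_forward(model$head, ef$emb[ia, , drop = FALSE],
                     ef$emb[ib, , drop = FALSE])
  ce <- softmax_ce(hf$logits, pairs$label)
  rev_logits <- head_forward(model$head, ef$emb[ib, , drop = FALSE],
                             ef$emb[ia, , drop = FALSE])$logits
  scores <- (softmax_rows(hf$logits)[, 2] + softmax_rows(rev_logits)[, 2]) / 2
  list(loss = ce$loss, scores = scores)
}

#' Train the pair classifier
#'
#' Minimises two-class cross-entropy with Adam or SGD. The featurization and
#' descriptor scaling must already have been fitted on the training drugs
#' only (see [fit_featurizer()]). Per epoch, the history records training
#' loss and validation loss/AUC/accuracy; the weights with the best
#' validation loss are returned. Fully reproducible given `cfg$seed`.
#'
#' @param model A `pair_classifier`.
#' @param images Named list (drug id -> normalized image matrix) covering all
#'   drugs in both partitions.
#' @param train_pairs,val_pairs Pair data.frames (drug_a, drug_b, label).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best-validation weights), `history`
#'   (data.frame: epoch, train_loss, val_loss, val_auc, val_acc) and
#'   `best_epoch`.
#' @export
train <- function(model, images, train_pairs, val_pairs, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "pair_classifier"), inherits(cfg, "train_config"),
            nrow(train_pairs) >= 1, nrow(val_pairs) >= 1)
  model$head$dropout_p <- cfg$dropout_p
  set.seed(cfg$seed)
  side <- nrow(images[[train_pairs$drug_a[1]]])
  state <- new_optimizer_state(model, cfg)
  n <- nrow(train_pairs)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auc = numeric(0),
                        val_acc = numeric(0))
  best <- list(loss = Inf, model = model, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      take <- ord[start:min(start + cfg$batch_size - 1L, n)]
      st <- train_step(model, images, train_pairs[take, , drop = FALSE], side)
      opt <- optimizer_step(st$model, st$grads, state, cfg)
      model <- opt$model
      state <- opt$state
      losses <- c(losses, st$loss)
    }
    vp <- validation_pass(model, images, val_pairs)
    vm <- compute_metrics(val_pairs$label, vp$scores)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses), val_loss = vp$loss,
      val_auc = vm$auc, val_acc = vm$accuracy))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f | val %.4f auc %.3f acc %.3f",
                      epoch, mean(losses), vp$loss, vm$auc, vm$accuracy))
    }
    if (vp$loss < best$loss) {
      best <- list(loss = vp$loss, model = model, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  list(model = best$model, history = history, best_epoch = best$epoch)
}

#' Evaluate a trained model on a held-out pair partition
#'
#' Scores every pair with the symmetric (order-averaged) probability and
#' computes the six-metric report. Deterministic given the model.
#'
#' @param model A trained `pair_classifier`.
#' @param images Named list of normalized image matrices.
#' @param test_pairs Pair data.frame.
#' @param threshold Decision threshold.
#' @return A `metrics_report`.
#' @export
evaluate <- function(model, images, test_pairs, threshold = 0.5) {
  if (is.null(test_pairs) || nrow(test_pairs) == 0L) {
    stop(ddimage_config_error("empty test partition"))
  }
  scores <- predict_pairs(model, images, test_pairs)
  compute_metrics(test_pairs$label, scores, threshold)
}

# -- ablation ----------------------------------------------------------------

#' Run the feature ablation harness
#'
#' Trains and evaluates one model per feature strategy on the same split
#' (identical seed, identical partitions), mirroring the five-way feature
#' ablation design: descriptor panels of 3/6/12, fingerprint alone, and
#' fingerprint + 12 descriptors.
#'
#' @param drugs Drug table (data.frame: drug_id, smiles).
#' @param pairs Pair table (data.frame: drug_a, drug_b, label).
#' @param strategies Character vector from [FEATURE_STRATEGIES].
#' @param split_cfg A [split_config()] shared by all strategies.
#' @param train_cfg A [train_config()] shared by all strategies.
#' @param spec An [image_tensor_spec()].
#' @param radius,n_bits Fingerprint parameters.
#' @param verbose Print progress.
#' @return List with `table` (one row per strategy: strategy, Pre, Rec, F1,
#'   AUPR, AUC, Acc) and `reports` (named list of `metrics_report`).
#' @export
run_ablation <- function(drugs, pairs, strategies = FEATURE_STRATEGIES,
                         split_cfg = split_config(),
                         train_cfg = train_config(),
                         spec = image_tensor_spec(target_side = 46L),
                         radius = 2L, n_bits = 2048L, verbose = FALSE) {
  bad <- setdiff(strategies, FEATURE_STRATEGIES)
  if (length(bad) > 0L) {
    stop(ddimage_config_error(paste0("unknown strategy: ",
                                     paste(bad, collapse = ", "))))
  }
  flt <- filter_invalid(drugs)
  mols <- flt$valid
  splits <- split_dataset(pairs, split_cfg)
  train_ids <- unique(c(splits$train$drug_a, splits$train$drug_b))
  reports <- list()
  for (strat in strategies) {
    if (verbose) message("ablation strategy: ", strat)
    ftz <- fit_featurizer(mols, strat, train_ids, radius, n_bits)
    images <- prepare_images(ftz, mols, spec)
    model <- new_pair_classifier(dropout_p = train_cfg$dropout_p,
                                 seed = train_cfg$seed)
    fit <- train(model, images, splits$train, splits$val, train_cfg,
                 verbose = verbose)
    reports[[strat]] <- evaluate(fit$model, images, splits$test)
  }
  tab <- cbind(data.frame(strategy = names(reports)),
               do.call(rbind, lapply(reports, metrics_row)))
  rownames(tab) <- NULL
  list(table = tab, reports = reports)
}

# -- logistic-regression baseline --------------------------------------------

#' Logistic-regression baseline on concatenated pair feature vectors
#'
#' L2-regularised logistic regression (ridge penalty, fixed small lambda) on
#' `concat(features_a, features_b)`, using the same feature vectors and the
#' same split as the network. Symmetrised like the network: the reported
#' score averages both concatenation orders.
#'
#' @param feats Feature matrix, one row per drug (see [feature_matrix()]).
#' @param splits The partition list from [split_dataset()].
#' @param lambda Ridge penalty (default 1e-3).
#' @return A `metrics_report` (with `converged` attribute; non-convergence is
#'   flagged in `undefined` as "convergence").
#' @export
baseline_logreg <- function(feats, splits, lambda = 1e-3) {
  pair_x <- function(pairs) {
    cbind(feats[pairs$drug_a, , drop = FALSE],
          feats[pairs$drug_b, , drop = FALSE])
  }
  x_train <- pair_x(splits$train)
  y_train <- splits$train$label
  fit <- glmnet::glmnet(x_train, factor(y_train, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  converged <- isTRUE(fit$jerr == 0)
  x_test <- pair_x(splits$test)
  x_test_rev <- cbind(feats[splits$test$drug_b, , drop = FALSE],
                      feats[splits$test$drug_a, , drop = FALSE])
  p <- (drop(stats::predict(fit, x_test, type = "response")) +
        drop(stats::predict(fit, x_test_rev, type = "response"))) / 2
  report <- compute_metrics(splits$test$label, p)
  if (!converged) report$undefined <- c(report$undefined, "convergence")
  attr(report, "converged") <- converged
  report
}
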