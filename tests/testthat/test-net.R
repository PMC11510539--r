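# helpers reaching into unexported layer internals
ns <- asNamespace("ddimage")

test_that("layer backward passes match numerical gradients", {
  set.seed(42)
  side <- 8L; N <- 3L
  X <- matrix(rnorm(side * side * N), ncol = 1)
  Wc <- ns$he_conv(3L, 1L, 4L)
  bn <- ns$new_bn(4L)
  lin <- ns$he_linear(4L, 2L)
  labels <- c(0L, 1L, 1L)
  fwd <- function(Wc, gamma, beta, Wl, X) {
    g <- ns$conv_geom(side, side, N, 3L, 1L, 1L)
    cf <- ns$conv_fwd(X, g, Wc)
    bnl <- list(gamma = gamma, beta = beta, running_mean = rep(0, 4),
                running_var = rep(1, 4))
    bf <- ns$bn_fwd(cf$out, bnl, training = TRUE)
    rf <- ns$relu_fwd(bf$out)
    g2 <- ns$conv_geom(side, side, N, 3L, 2L, 1L)
    mp <- ns$maxpool_fwd(rf$out, g2)
    gp <- ns$gap_fwd(mp$out, g2$Ho, g2$Wo, N)
    lf <- ns$linear_fwd(gp$out, Wl, lin$b)
    ce <- ns$softmax_ce(lf$out, labels)
    list(loss = ce$loss, cf = cf, bf = bf, rf = rf, mp = mp, gp = gp,
         lf = lf, ce = ce)
  }
  f <- fwd(Wc, bn$gamma, bn$beta, lin$W, X)
  lb <- ns$linear_bwd(f$ce$dlogits, f$lf$cache, lin$W)
  dgap <- ns$gap_bwd(lb$dX, f$gp$cache)
  dmp <- ns$maxpool_bwd(dgap, f$mp$cache)
  dr <- ns$relu_bwd(dmp, f$rf$cache)
  bb <- ns$bn_bwd(dr, f$bf$cache, list(gamma = bn$gamma))
  cb <- ns$conv_bwd(bb$dX, f$cf$cache, Wc)

  numcheck <- function(analytic, theta, lossfun, n = 6) {
    idx <- sample(length(theta), min(n, length(theta)))
    for (i in idx) {
      e <- 1e-5
      t1 <- theta; t1[i] <- theta[i] + e
      t2 <- theta; t2[i] <- theta[i] - e
      ng <- (lossfun(t1) - lossfun(t2)) / (2 * e)
      expect_equal(analytic[i], ng, tolerance = 1e-4)
    }
  }
  numcheck(cb$dW, Wc,
           function(t) fwd(matrix(t, nrow(Wc)), bn$gamma, bn$beta,
                           lin$W, X)$loss)
  numcheck(bb$dgamma, bn$gamma,
           function(t) fwd(Wc, t, bn$beta, lin$W, X)$loss)
  numcheck(bb$dbeta, bn$beta,
           function(t) fwd(Wc, bn$gamma, t, lin$W, X)$loss)
  numcheck(lb$dW, lin$W,
           function(t) fwd(Wc, bn$gamma, bn$beta, matrix(t, 4, 2), X)$loss)
  numcheck(cb$dX, X,
           function(t) fwd(Wc, bn$gamma, bn$beta, lin$W,
                           matrix(t, ncol = 1))$loss)
})

test_that("zeroed residual branch reduces identity-skip blocks to ReLU", {
  set.seed(5)
  model <- zero_residual_branches(new_pair_classifier(seed = 5))
  blk <- model$encoder$blocks[[1]]  # 64 -> 64, stride 1, identity skip
  H <- 6L; W <- 6L; N <- 2L
  X <- matrix(rnorm(H * W * N * 64), ncol = 64)
  out <- residual_block_forward(X, blk, H, W, N, training = FALSE)
  expect_identical(out$out, pmax(X, 0))

  # non-negative input passes through exactly (F(x)=0 => H(x)=x)
  Xp <- abs(X)
  expect_identical(residual_block_forward(Xp, blk, H, W, N)$out, Xp)

  # all-negative input collapses to zero under the final ReLU
  Xn <- -abs(X)
  expect_true(all(residual_block_forward(Xn, blk, H, W, N)$out == 0))

  # stacked identity-skip blocks telescope: x_L == x_1 for x_1 >= 0
  b2 <- model$encoder$blocks[[2]]
  o1 <- residual_block_forward(Xp, blk, H, W, N)
  o2 <- residual_block_forward(o1$out, b2, H, W, N)
  expect_identical(o2$out, Xp)

  expect_error(residual_block_forward(X[, 1:32], blk, H, W, N),
               class = "ddimage_shape_error")
})

test_that("encoder emits 512-dim embeddings and rejects tiny images", {
  set.seed(6)
  enc <- new_encoder()
  for (side in c(32L, 46L)) {
    X <- matrix(rnorm(side * side), side, side)
    ef <- encoder_forward(enc, X, side)
    expect_equal(dim(ef$emb), c(1L, 512L))
    expect_true(all(is.finite(ef$emb)))
  }
  expect_error(encoder_forward(enc, matrix(0, 31, 31), 31L),
               class = "ddimage_shape_error")
  # eval-mode determinism
  X <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(encoder_forward(enc, X, 32L)$emb,
                   encoder_forward(enc, X, 32L)$emb)
  # different random initialisations embed differently
  set.seed(1); e1 <- new_encoder()
  set.seed(2); e2 <- new_encoder()
  expect_false(identical(encoder_forward(e1, X, 32L)$emb,
                         encoder_forward(e2, X, 32L)$emb))
})

test_that("parameter counts match the 18-layer residual layout arithmetic", {
  model <- new_pair_classifier(seed = 1)
  # independent arithmetic: stem 7x7x1x64 conv + BN(2*64); blocks as
  # conv3x3 pairs + BNs (+ 1x1 projection + BN at each width change)
  bn_p <- function(C) 2 * C
  block_p <- function(cin, cout, proj) {
    9 * cin * cout + bn_p(cout) + 9 * cout * cout + bn_p(cout) +
      if (proj) cin * cout + bn_p(cout) else 0
  }
  expected_encoder <- 49 * 1 * 64 + bn_p(64) +
    block_p(64, 64, FALSE) + block_p(64, 64, FALSE) +
    block_p(64, 128, TRUE) + block_p(128, 128, FALSE) +
    block_p(128, 256, TRUE) + block_p(256, 256, FALSE) +
    block_p(256, 512, TRUE) + block_p(512, 512, FALSE)
  expect_equal(count_parameters(model, encoder_only = TRUE), expected_encoder)
  expect_equal(expected_encoder, 11170240)  # regression constant
  expected_head <- 1024 * 1024 + 1024 + 1024 * 2 + 2
  expect_equal(count_parameters(model), expected_encoder + expected_head)
})

test_that("pair head consumes 1024 concatenated features and emits 2 logits", {
  set.seed(9)
  model <- new_pair_classifier(seed = 9)
  expect_equal(dim(model$head$fc1$W), c(1024L, 1024L))
  expect_equal(dim(model$head$fc2$W), c(1024L, 2L))
  a <- matrix(rnorm(32 * 32), 32, 32)
  b <- matrix(rnorm(32 * 32), 32, 32)
  lg <- pair_forward(model, a, b)
  expect_length(lg, 2)
  expect_true(all(is.finite(lg)))
  # eval mode: repeated calls identical (dropout disabled)
  expect_identical(lg, pair_forward(model, a, b))
})

test_that("predict_proba is symmetric and normalised", {
  set.seed(10)
  model <- new_pair_classifier(seed = 10)
  a <- matrix(rnorm(32 * 32), 32, 32)
  b <- matrix(rnorm(32 * 32), 32, 32)
  p <- predict_proba(model, a, b)
  expect_equal(p, predict_proba(model, b, a))
  expect_gte(p, 0); expect_lte(p, 1)
  # softmax rows sum to one
  pr <- ns$softmax_rows(matrix(pair_forward(model, a, b), 1))
  expect_equal(sum(pr), 1)
  # zeroed head gives logits (0, 0) in both orders, hence probability 1/2
  z <- model
  z$head$fc1$W[] <- 0; z$head$fc1$b[] <- 0
  z$head$fc2$W[] <- 0; z$head$fc2$b[] <- 0
  expect_equal(predict_proba(z, a, b), 0.5)
})

test_that("one backward pass reaches every learnable parameter", {
  set.seed(12)
  model <- new_pair_classifier(dropout_p = 0, seed = 12)
  images <- random_images(6, 32, seed = 12)
  pairs <- random_pairs(names(images), 10, seed = 12)
  st <- ns$train_step(model, images, pairs, 32L)
  for (p in ns$param_paths(model)) {
    g <- ns$pluck(st$grads, p)
    expect_true(all(is.finite(g)),
                label = paste(unlist(p), collapse = "."))
    expect_gt(sum(g != 0), 0)
  }
})

test_that("checkpoints round-trip weights, config and seed", {
  set.seed(13)
  model <- new_pair_classifier(seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, config = list(note = "t", lr = 1e-3),
                  seed = 13L)
  ck <- load_checkpoint(path)
  expect_equal(ck$seed, 13L)
  expect_equal(ck$config$lr, 1e-3)
  a <- matrix(rnorm(32 * 32), 32, 32)
  b <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(predict_proba(ck$model, a, b), predict_proba(model, a, b))
  expect_true(file.exists(paste0(path, ".json")))

  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("corrupted", bad)
  expect_error(load_checkpoint(bad), class = "ddimage_config_error")
})
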