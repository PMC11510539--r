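# Minimal CNN layer library (forward + backward).
#
# Activations are stored channels-last as a (H*W*N) x C matrix with row index
# r = i + (j-1)*H + (n-1)*H*W. Convolution and pooling use an im2col patch
# matrix built from k*k cached index slices of the zero-padded activation;
# the memory movement and elementwise math live in src/ops.cpp and the
# matrix products in the BLAS. For a fixed kernel offset the map from output
# position to padded input row is injective, so the col2im backward pass is
# k*k plain indexed additions with no scatter conflicts. Everything is
# deterministic given the R RNG state.

conv_out_side <- function(side, k, s, p) (side + 2L * p - k) %/% s + 1L

.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(H, W, N, k, s, p) {
  key <- paste(H, W, N, k, s, p, sep = ",")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- conv_out_side(H, k, s, p); Wo <- conv_out_side(W, k, s, p)
  plane <- Hp * Wp
  interior <- as.integer(outer(
    outer((p + 1L):(p + H), ((p + 1L):(p + W) - 1L) * Hp, "+"),
    (0:(N - 1L)) * plane, "+"))
  offsets <- matrix(0L, k * k, Ho * Wo * N)
  o <- 0L
  for (dj in 1:k) {
    for (di in 1:k) {
      o <- o + 1L
      offsets[o, ] <- as.integer(outer(
        outer((0:(Ho - 1L)) * s + di, ((0:(Wo - 1L)) * s + dj - 1L) * Hp, "+"),
        (0:(N - 1L)) * plane, "+"))
    }
  }
  g <- list(H = H, W = W, N = N, k = k, s = s, p = p, Hp = Hp, Wp = Wp,
            Ho = Ho, Wo = Wo, rows = Hp * Wp * N, interior = interior,
            offsets = offsets)
  .geom_cache[[key]] <- g
  g
}

# weight matrix Wm is (k*k*Cin) x Cout, rows offset-major (offset block o
# holds channels 1..Cin); no bias (convs are always followed by batch norm)
conv_fwd <- function(X, geom, Wm) {
  Xp <- if (geom$p > 0L) cpp_pad_rows(X, geom$interior, geom$rows, 0) else X
  cf <- cpp_conv_fwd(Xp, Wm, geom$offsets)
  list(out = cf$out, cache = list(P = cf$P, geom = geom))
}

conv_bwd <- function(dY, cache, Wm) {
  geom <- cache$geom
  cb <- cpp_conv_bwd(dY, cache$P, Wm, geom$offsets, geom$rows)
  dX <- if (geom$p > 0L) cpp_unpad_rows(cb$dXp, geom$interior) else cb$dXp
  list(dX = dX, dW = cb$dW)
}

.BN_EPS <- 1e-5

bn_fwd <- function(X, bn, training, momentum = 0.1) {
  if (training) {
    mu <- .colMeans(X, nrow(X), ncol(X))
    v <- .colMeans(X * X, nrow(X), ncol(X)) - mu * mu
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  invstd <- 1 / sqrt(v + .BN_EPS)
  ap <- cpp_bn_apply(X, bn$gamma, bn$beta, mu, invstd)
  list(out = ap$out, bn = bn,
       cache = list(xhat = ap$xhat, invstd = invstd, training = training))
}

bn_bwd <- function(dY, cache, bn) {
  r <- cpp_bn_bwd(dY, cache$xhat, bn$gamma, cache$invstd, cache$training)
  list(dX = r$dX, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fwd <- function(X) {
  out <- cpp_relu_fwd(X)
  list(out = out, cache = out)
}

relu_bwd <- function(dY, out) cpp_relu_bwd(dY, out)

maxpool_fwd <- function(X, geom) {
  Xp <- cpp_pad_rows(X, geom$interior, geom$rows, -Inf)
  mp <- cpp_maxpool_fwd(Xp, geom$offsets)
  list(out = mp$out, cache = list(argm = mp$argm, geom = geom))
}

maxpool_bwd <- function(dY, cache) {
  geom <- cache$geom
  dXp <- cpp_maxpool_bwd(dY, cache$argm, geom$offsets, geom$rows)
  cpp_unpad_rows(dXp, geom$interior)
}

# global average pool: (H*W*N) x C -> N x C
gap_fwd <- function(X, H, W, N) {
  plane <- H * W
  out <- rowsum(X, rep(seq_len(N), each = plane), reorder = FALSE) / plane
  list(out = out, cache = list(H = H, W = W, N = N))
}

gap_bwd <- function(dY, cache) {
  plane <- cache$H * cache$W
  dY[rep(seq_len(cache$N), each = plane), , drop = FALSE] / plane
}

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}

linear_bwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

# inverted dropout; draws from the R RNG so runs are seed-reproducible
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# softmax cross-entropy on two-logit rows; labels are 0/1 (column label+1)
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  shifted <- logits - apply(logits, 1, max)
  ez <- exp(shifted)
  probs <- ez / rowSums(ez)
  picked <- probs[cbind(seq_len(n), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  list(loss = loss, probs = probs, dlogits = (probs - onehot) / n)
}

softmax_rows <- function(logits) {
  shifted <- logits - apply(logits, 1, max)
  ez <- exp(shifted)
  ez / rowSums(ez)
}
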