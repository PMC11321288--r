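# Minimal convolutional network machinery backing the self-supervised
# feature extractor: strided 3x3 conv blocks with batch normalization and
# ReLU, global average pooling, and two-layer MLP heads. Forward and
# backward passes are hand-written; the im2col/col2im gathers run in
# compiled code (see src/), everything else is BLAS matrix algebra.
#
# Layout convention: a batch of feature maps is a (H*W*C x B) matrix, one
# column per image, rows ordered row-fastest, then column, then channel.

.bn_eps <- 1e-5

# Precompute im2col geometry for one conv layer. Indices are 0-based into
# the unpadded image; out-of-bounds kernel taps carry a -1 sentinel that
# the compiled gather/scatter kernels treat as zero padding.
conv_geom <- function(H, W, C, K = 3L, stride = 2L, pad = 1L) {
  Ho <- (H + 2L * pad - K) %/% stride + 1L
  Wo <- (W + 2L * pad - K) %/% stride + 1L
  P <- Ho * Wo
  or <- rep(seq_len(Ho), times = Wo)
  oc <- rep(seq_len(Wo), each = Ho)
  r0 <- (or - 1L) * stride - pad        # 0-based top-left of each window
  c0 <- (oc - 1L) * stride - pad
  kr <- rep(seq_len(K), times = K) - 1L
  kc <- rep(seq_len(K), each = K) - 1L
  rr <- outer(kr, r0, "+")              # (K*K x P) 0-based rows
  cc <- outer(kc, c0, "+")
  valid <- rr >= 0 & rr < H & cc >= 0 & cc < W
  base <- rr + cc * H
  KK <- K * K
  idx <- matrix(-1L, KK * C, P)
  for (ch in seq_len(C)) {
    b <- base + (ch - 1L) * H * W
    b[!valid] <- -1L
    idx[((ch - 1L) * KK + 1L):(ch * KK), ] <- as.integer(b)
  }
  list(H = H, W = W, C = C, K = K, stride = stride, pad = pad,
       Ho = Ho, Wo = Wo, P = P, KKC = KK * C, M = H * W * C,
       idx0 = as.integer(idx))
}

# Architecture descriptor for the encoder + MLP heads.
encoder_arch <- function(input_hw = c(64L, 64L), channels = c(8L, 16L, 32L, 64L),
                         kernel = 3L, stride = 2L,
                         proj_hidden = 256L, proj_dim = 64L) {
  stopifnot(length(input_hw) == 2, all(input_hw >= 16), length(channels) >= 2)
  H <- as.integer(input_hw[1]); W <- as.integer(input_hw[2])
  Cin <- 1L
  geoms <- vector("list", length(channels))
  for (l in seq_along(channels)) {
    geoms[[l]] <- conv_geom(H, W, Cin, kernel, stride, pad = 1L)
    H <- geoms[[l]]$Ho; W <- geoms[[l]]$Wo; Cin <- as.integer(channels[l])
  }
  list(input_hw = as.integer(input_hw), channels = as.integer(channels),
       kernel = as.integer(kernel), stride = as.integer(stride),
       geoms = geoms, D = as.integer(channels[length(channels)]),
       proj_hidden = as.integer(proj_hidden), proj_dim = as.integer(proj_dim))
}

init_conv_params <- function(arch) {
  lapply(seq_along(arch$channels), function(l) {
    g <- arch$geoms[[l]]
    Cout <- arch$channels[l]
    list(W = matrix(stats::rnorm(g$KKC * Cout, sd = sqrt(2 / g$KKC)), g$KKC, Cout),
         gamma = rep(1, Cout), beta = rep(0, Cout))
  })
}

init_mlp_params <- function(d_in, d_hidden, d_out) {
  list(W1 = matrix(stats::rnorm(d_in * d_hidden, sd = sqrt(2 / d_in)), d_in, d_hidden),
       b1 = rep(0, d_hidden),
       gamma = rep(1, d_hidden), beta = rep(0, d_hidden),
       W2 = matrix(stats::rnorm(d_hidden * d_out, sd = sqrt(2 / d_hidden)), d_hidden, d_out),
       b2 = rep(0, d_out))
}

init_running_stats <- function(arch) {
  lapply(arch$channels, function(c) list(mean = rep(0, c), var = rep(1, c)))
}

# scale a (n x C) matrix per column: x * a[col] + b[col]
.col_affine <- function(x, a, b = NULL) {
  n <- nrow(x)
  out <- x * rep(a, each = n)
  if (!is.null(b)) out <- out + rep(b, each = n)
  out
}

# Encoder forward pass. X: (H*W x B). Returns pooled (B x D) features,
# per-layer caches when keep_cache, per-layer post-ReLU activations when
# keep_acts, and batch-norm batch statistics for running-stat updates.
enc_forward <- function(arch, params, X, training = TRUE, running = NULL,
                        keep_cache = FALSE, keep_acts = FALSE) {
  B <- ncol(X)
  caches <- if (keep_cache) vector("list", length(arch$channels)) else NULL
  acts <- if (keep_acts) vector("list", length(arch$channels)) else NULL
  bstats <- vector("list", length(arch$channels))
  A <- X
  none <- numeric(0)
  for (l in seq_along(arch$channels)) {
    g <- arch$geoms[[l]]
    Cout <- arch$channels[l]
    Xcol <- nn_im2col(A, g$idx0, g$KKC, g$P)
    Z <- crossprod(Xcol, params[[l]]$W)           # (P*B x Cout)
    bn <- nn_bn_relu_fwd(Z, params[[l]]$gamma, params[[l]]$beta, training,
                         if (training) none else running[[l]]$mean,
                         if (training) none else running[[l]]$var, .bn_eps)
    out <- bn$out
    if (training) bstats[[l]] <- list(mean = bn$mu, var = bn$var)
    if (keep_cache) {
      caches[[l]] <- list(Xcol = Xcol, Z = Z, out = out, mu = bn$mu,
                          var = bn$var, B = B, training = training)
    }
    if (keep_acts) {
      a <- out
      dim(a) <- c(g$P, B, Cout)
      acts[[l]] <- a                                # (P x B x Cout)
    }
    A <- nn_to_planes(out, g$P, B, Cout)
  }
  gl <- arch$geoms[[length(arch$geoms)]]
  P_last <- gl$P
  D <- arch$D
  pooled <- rowsum(A, group = rep(seq_len(D), each = P_last)) / P_last  # (D x B)
  list(out = t(pooled), caches = caches, acts = acts, bstats = bstats,
       P_last = P_last)
}

# Backward through the encoder. dPooled: (B x D). Returns conv parameter
# gradients (same shape as params); optionally the per-layer activation
# gradients (for GradCAM) and the input gradient.
enc_backward <- function(arch, params, fw, dPooled, keep_act_grads = FALSE) {
  nl <- length(arch$channels)
  grads <- vector("list", nl)
  act_grads <- if (keep_act_grads) vector("list", nl) else NULL
  D <- arch$D
  M <- t(dPooled) / fw$P_last                       # (D x B)
  dA <- M[rep(seq_len(D), each = fw$P_last), , drop = FALSE]  # (P*D x B)
  for (l in rev(seq_len(nl))) {
    g <- arch$geoms[[l]]
    Cout <- arch$channels[l]
    cc <- fw$caches[[l]]
    dA <- nn_from_planes(dA, g$P, cc$B, Cout)
    if (keep_act_grads) {
      ag <- dA
      dim(ag) <- c(g$P, cc$B, Cout)
      act_grads[[l]] <- ag
    }
    bb <- nn_bn_relu_bwd(dA, cc$out, cc$Z, cc$mu, cc$var, params[[l]]$gamma,
                         isTRUE(cc$training), .bn_eps)
    dZ <- bb$dZ
    grads[[l]] <- list(W = cc$Xcol %*% dZ, gamma = bb$dgamma, beta = bb$dbeta)
    if (l > 1 || keep_act_grads) {
      dXcol <- params[[l]]$W %*% t(dZ)
      dA <- nn_col2im(dXcol, g$idx0, g$M, g$P)
    }
  }
  list(grads = grads, act_grads = act_grads, dX = if (keep_act_grads) dA else NULL)
}

# Two-layer MLP head with batch-norm + ReLU on the hidden layer.
mlp_forward <- function(params, X, training = TRUE, keep_cache = FALSE) {
  Z1 <- X %*% params$W1
  Z1 <- Z1 + rep(params$b1, each = nrow(Z1))
  n <- nrow(Z1)
  if (training && n > 1) {
    mu <- colMeans(Z1)
    v <- colMeans(Z1 * Z1) - mu * mu
  } else {
    mu <- rep(0, ncol(Z1)); v <- rep(1, ncol(Z1))
  }
  inv <- 1 / sqrt(v + .bn_eps)
  Xhat <- .col_affine(Z1, inv, -mu * inv)
  H1 <- .col_affine(Xhat, params$gamma, params$beta)
  relu <- H1 > 0
  H1[!relu] <- 0
  out <- H1 %*% params$W2
  out <- out + rep(params$b2, each = nrow(out))
  cache <- if (keep_cache) list(X = X, Xhat = Xhat, inv = inv, relu = relu,
                                H1 = H1, bn = training && n > 1) else NULL
  list(out = out, cache = cache)
}

mlp_backward <- function(params, cache, dOut) {
  dW2 <- crossprod(cache$H1, dOut)
  db2 <- colSums(dOut)
  dH1 <- tcrossprod(dOut, params$W2)
  dH1[!cache$relu] <- 0
  n <- nrow(dH1)
  dgamma <- colSums(dH1 * cache$Xhat)
  dbeta <- colSums(dH1)
  dXhat <- .col_affine(dH1, params$gamma)
  if (isTRUE(cache$bn)) {
    s1 <- colSums(dXhat) / n
    s2 <- colSums(dXhat * cache$Xhat) / n
    dZ1 <- .col_affine(dXhat - .col_affine(cache$Xhat, s2), cache$inv, -s1 * cache$inv)
  } else {
    dZ1 <- .col_affine(dXhat, cache$inv)
  }
  dW1 <- crossprod(cache$X, dZ1)
  db1 <- colSums(dZ1)
  dX <- tcrossprod(dZ1, params$W1)
  list(grads = list(W1 = dW1, b1 = db1, gamma = dgamma, beta = dbeta,
                    W2 = dW2, b2 = db2),
       dX = dX)
}

# --- nested parameter-list utilities -----------------------------------

param_map <- function(x, f) {
  if (is.list(x)) lapply(x, param_map, f = f) else f(x)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

# One Adam step with L2 weight decay folded into the gradient.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  if (weight_decay > 0) {
    grads <- param_map2(grads, params, function(g, p) g + weight_decay * p)
  }
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  step <- param_map2(state$m, state$v, function(m, v) {
    lr * (m / corr1) / (sqrt(v / corr2) + eps)
  })
  params <- param_map2(params, step, function(p, s) p - s)
  list(params = params, state = state)
}

sum_grads <- function(a, b) param_map2(a, b, `+`)
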