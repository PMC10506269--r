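# Batched network engine: forward pass with caching and exact analytic
# gradients. A batch of B feature maps of shape L x D is stored as one
# (L*B) x D matrix whose rows are sample-major blocks, row r = t + (b-1)*L.
# That layout keeps every step a BLAS call or an indexed gather/scatter and
# avoids per-layer array transposes. All functions here are internal; the
# user-facing layer API in layers.R is an independent single-sample reference
# path that the tests compare against.

mat3 <- function(X) {
  d <- dim(X)
  Y <- aperm(X, c(1L, 3L, 2L))
  dim(Y) <- c(d[1L] * d[3L], d[2L])
  Y
}

# ---- convolution ----------------------------------------------------------

# row indices of the unpadded positions inside the padded row-block layout
conv_base_idx <- function(L, B, p) {
  rep((seq_len(B) - 1L) * (L + 2L * p), each = L) + seq_len(L)
}

conv_fwd_batch <- function(X, W, b, k, L, B) {
  D_in <- ncol(X)
  p <- (k - 1L) %/% 2L
  base <- conv_base_idx(L, B, p)
  Xp <- matrix(0, (L + 2L * p) * B, D_in)
  Xp[base + p, ] <- X
  M <- matrix(0, L * B, k * D_in)
  for (j in seq_len(k)) {
    M[, ((j - 1L) * D_in + 1L):(j * D_in)] <- Xp[base + (j - 1L), , drop = FALSE]
  }
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, M = M)
}

conv_bwd_batch <- function(dY, cache, W, k, L, B, D_in) {
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  p <- (k - 1L) %/% 2L
  base <- conv_base_idx(L, B, p)
  dXp <- matrix(0, (L + 2L * p) * B, D_in)
  for (j in seq_len(k)) {
    r <- base + (j - 1L)
    dXp[r, ] <- dXp[r, , drop = FALSE] + dM[, ((j - 1L) * D_in + 1L):(j * D_in), drop = FALSE]
  }
  list(dX = dXp[base + p, , drop = FALSE], dW = dW, db = db)
}

# ---- multi-head self-attention -------------------------------------------

mha_fwd_batch <- function(X, att, n_heads, d_k, d_h, L, B) {
  Qa <- X %*% att$Wq
  Ka <- X %*% att$Wk
  Va <- X %*% att$Wv
  core <- mha_fwd_cpp(Qa, Ka, Va, n_heads, d_k, d_h, L, B)
  Out <- core$Hc %*% att$Wo
  list(Y = Out,
       cache = list(X = X, Qa = Qa, Ka = Ka, Va = Va, A = core$A, Hc = core$Hc))
}

mha_bwd_batch <- function(dY, cache, att, n_heads, d_k, d_h, L, B) {
  dWo <- crossprod(cache$Hc, dY)
  dHc <- tcrossprod(dY, att$Wo)
  core <- mha_bwd_cpp(cache$A, cache$Qa, cache$Ka, cache$Va, dHc,
                      n_heads, d_k, d_h, L, B)
  dX <- tcrossprod(core$dQa, att$Wq) + tcrossprod(core$dKa, att$Wk) +
    tcrossprod(core$dVa, att$Wv)
  list(dX = dX,
       dWq = crossprod(cache$X, core$dQa),
       dWk = crossprod(cache$X, core$dKa),
       dWv = crossprod(cache$X, core$dVa),
       dWo = dWo)
}

# ---- pooling --------------------------------------------------------------

pool_fwd_batch <- function(X, size, stride, L, B) {
  L_out <- (L - size) %/% stride + 1L
  starts <- (seq_len(L_out) - 1L) * stride + 1L
  idx <- rep((seq_len(B) - 1L) * L, each = L_out) + rep(starts, B)
  Y <- X[idx, , drop = FALSE]
  argo <- matrix(1L, nrow(Y), ncol(Y))
  if (size > 1L) {
    for (w in 2L:size) {
      cand <- X[idx + (w - 1L), , drop = FALSE]
      upd <- cand > Y
      Y[upd] <- cand[upd]
      argo[upd] <- w
    }
  }
  list(Y = Y, argo = argo, idx = idx, L_in = L, L_out = L_out)
}

pool_bwd_batch <- function(dY, cache, size, B) {
  dX <- matrix(0, cache$L_in * B, ncol(dY))
  for (w in seq_len(size)) {
    g <- dY * (cache$argo == w)
    r <- cache$idx + (w - 1L)
    dX[r, ] <- dX[r, , drop = FALSE] + g
  }
  dX
}

# ---- CAC layer ------------------------------------------------------------

cac_fwd_batch <- function(X, layer_cfg, layer_par, L, B) {
  stopifnot(sum(vapply(layer_cfg$branches, `[[`, integer(1L), "d_out")) == layer_cfg$D)
  H <- matrix(0, L * B, layer_cfg$D)
  caches <- vector("list", layer_cfg$i)
  off <- 0L
  for (j in seq_len(layer_cfg$i)) {
    bc <- layer_cfg$branches[[j]]
    bp <- layer_par[[j]]
    cv <- conv_fwd_batch(X, bp$conv$W, bp$conv$b, bc$kernel_size, L, B)
    at <- mha_fwd_batch(X, bp$att, bc$n_heads, bc$d_k, bc$d_h, L, B)
    Z <- cbind(cv$Y, at$Y)
    mask <- Z > 0                      # ReLU
    H[, off + seq_len(bc$d_out)] <- Z * mask
    off <- off + bc$d_out
    caches[[j]] <- list(conv = cv["M"], att = at$cache, mask = mask)
  }
  list(Y = H, cache = caches)
}

cac_bwd_batch <- function(dH, cache, layer_cfg, layer_par, L, B) {
  D_in <- layer_cfg$input_channels
  dX <- matrix(0, L * B, D_in)
  grads <- vector("list", layer_cfg$i)
  off <- 0L
  for (j in seq_len(layer_cfg$i)) {
    bc <- layer_cfg$branches[[j]]
    bp <- layer_par[[j]]
    dZ <- dH[, off + seq_len(bc$d_out), drop = FALSE] * cache[[j]]$mask
    off <- off + bc$d_out
    gc <- conv_bwd_batch(dZ[, seq_len(bc$d_conv), drop = FALSE], cache[[j]]$conv,
                         bp$conv$W, bc$kernel_size, L, B, D_in)
    ga <- mha_bwd_batch(dZ[, bc$d_conv + seq_len(bc$d_v), drop = FALSE],
                        cache[[j]]$att, bp$att, bc$n_heads, bc$d_k, bc$d_h, L, B)
    dX <- dX + gc$dX + ga$dX
    grads[[j]] <- list(
      conv = list(W = gc$dW, b = gc$db),
      att = list(Wq = ga$dWq, Wk = ga$dWk, Wv = ga$dWv, Wo = ga$dWo)
    )
  }
  list(dX = dX, grads = grads)
}

# flatten (L*B) x D -> B x (L*D) with position fastest within each channel
flat_fwd <- function(X, L, B) {
  D <- ncol(X)
  a <- X
  dim(a) <- c(L, B, D)
  a <- aperm(a, c(1L, 3L, 2L))
  dim(a) <- c(L * D, B)
  t(a)
}

flat_bwd <- function(dF, L, D, B) {
  a <- t(dF)
  dim(a) <- c(L, D, B)
  a <- aperm(a, c(1L, 3L, 2L))
  dim(a) <- c(L * B, D)
  a
}

# ---- full network ---------------------------------------------------------

# Forward pass over a batch. X: (L, 4, B) array or the row-blocked matrix
# with attributes L, B given explicitly. Returns probabilities (B x C); with
# cache = TRUE also everything needed for the backward pass. Dropout masks
# are drawn from the current RNG stream when training = TRUE.
engine_forward <- function(model, X, training = FALSE, cache = FALSE) {
  cfg <- model$config
  par <- model$params
  stopifnot(is.array(X), length(dim(X)) == 3L)
  L <- dim(X)[1L]; B <- dim(X)[3L]
  H <- mat3(X)
  cc <- list(pools = list(), layers = list())
  for (l in seq_along(cfg$layers)) {
    fw <- cac_fwd_batch(H, cfg$layers[[l]], par$layers[[l]], L, B)
    if (cache) cc$layers[[l]] <- fw$cache
    H <- fw$Y
    if (l %in% cfg$pool_after) {
      pw <- pool_fwd_batch(H, cfg$pool$size, cfg$pool$stride, L, B)
      if (cache) cc$pools[[l]] <- pw[c("argo", "idx", "L_in")]
      H <- pw$Y
      L <- pw$L_out
    }
  }
  flat <- flat_fwd(H, L, B)
  if (training && cfg$dropout_feature > 0) {
    keep <- 1 - cfg$dropout_feature
    m0 <- (matrix(stats::runif(length(flat)), nrow(flat)) < keep) / keep
    flat <- flat * m0
    if (cache) cc$drop0 <- m0
  }
  H1 <- relu(flat %*% par$fc$W1 + rep(par$fc$b1, each = B))
  H1d <- H1
  if (training && cfg$dropout_fc > 0) {
    keep <- 1 - cfg$dropout_fc
    m1 <- (matrix(stats::runif(length(H1)), nrow(H1)) < keep) / keep
    H1d <- H1 * m1
    if (cache) cc$drop1 <- m1
  }
  logits <- H1d %*% par$fc$W2 + rep(par$fc$b2, each = B)
  prob <- sigmoid(logits)
  if (!cache) return(list(prob = prob, logits = logits))
  cc$flat <- flat
  cc$H1 <- H1
  cc$H1d <- H1d
  cc$L_final <- L
  list(prob = prob, logits = logits, cache = cc)
}

# Backward pass from d(loss)/d(logits). Returns a gradient tree mirroring
# model$params (plus dX, the gradient w.r.t. the one-hot input).
engine_backward <- function(model, X, cc, dlogits) {
  cfg <- model$config
  par <- model$params
  B <- nrow(dlogits)
  g <- list(layers = vector("list", length(cfg$layers)), fc = list())
  g$fc$W2 <- crossprod(cc$H1d, dlogits)
  g$fc$b2 <- colSums(dlogits)
  dH1d <- tcrossprod(dlogits, par$fc$W2)
  if (!is.null(cc$drop1)) dH1d <- dH1d * cc$drop1
  dH1 <- dH1d * (cc$H1 > 0)
  g$fc$W1 <- crossprod(cc$flat, dH1)
  g$fc$b1 <- colSums(dH1)
  dflat <- tcrossprod(dH1, par$fc$W1)
  if (!is.null(cc$drop0)) dflat <- dflat * cc$drop0
  L <- cc$L_final
  dH <- flat_bwd(dflat, L, cfg$layers[[length(cfg$layers)]]$D, B)
  for (l in rev(seq_along(cfg$layers))) {
    if (l %in% cfg$pool_after) {
      dH <- pool_bwd_batch(dH, cc$pools[[l]], cfg$pool$size, B)
      L <- cc$pools[[l]]$L_in
    }
    bw <- cac_bwd_batch(dH, cc$layers[[l]], cfg$layers[[l]], par$layers[[l]], L, B)
    g$layers[[l]] <- bw$grads
    dH <- bw$dX
  }
  g$dX <- dH
  g
}
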