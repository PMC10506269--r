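# Independent oracle implementations used to cross-check the package: plain
# loops and direct enumerations, deliberately sharing no code with the
# implementation paths they verify.

rmat <- function(n, m, sd = 1) matrix(rnorm(n * m, sd = sd), n, m)

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

# direct exp/sum softmax, no max subtraction
oracle_softmax <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- exp(m[i, ]) / sum(exp(m[i, ]))
  out
}

# triple-loop single-head attention
oracle_single_head <- function(X, W_q, W_k, W_v) {
  L <- nrow(X)
  Q <- X %*% W_q; K <- X %*% W_k; V <- X %*% W_v
  d_k <- ncol(W_q)
  S <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      s <- 0
      for (d in seq_len(d_k)) s <- s + Q[i, d] * K[j, d]
      S[i, j] <- s / sqrt(d_k)
    }
  }
  A <- oracle_softmax(S)
  out <- matrix(0, L, ncol(W_v))
  for (i in seq_len(L)) {
    for (d in seq_len(ncol(W_v))) out[i, d] <- sum(A[i, ] * V[, d])
  }
  out
}

# head-by-head composition + explicit concat + W_o
oracle_mha <- function(X, p) {
  H <- NULL
  for (h in p$heads) H <- cbind(H, oracle_single_head(X, h$W_q, h$W_k, h$W_v))
  H %*% p$W_o
}

# sliding-window loop convolution with zero "same" padding
oracle_conv <- function(X, kernels, bias) {
  L <- nrow(X); k <- dim(kernels)[1L]; D_in <- dim(kernels)[2L]
  d_conv <- dim(kernels)[3L]
  pad <- (k - 1L) / 2L
  Xp <- rbind(matrix(0, pad, D_in), X, matrix(0, pad, D_in))
  out <- matrix(0, L, d_conv)
  for (t in seq_len(L)) {
    for (f in seq_len(d_conv)) {
      acc <- bias[f]
      for (j in seq_len(k)) {
        for (c in seq_len(D_in)) acc <- acc + Xp[t + j - 1L, c] * kernels[j, c, f]
      }
      out[t, f] <- acc
    }
  }
  out
}

# O(n^2) pairwise Mann-Whitney AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# direct enumeration of the sorted list
oracle_ap <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  tp <- 0; s <- 0; prev_r <- 0; npos <- sum(labels)
  for (i in seq_along(y)) {
    tp <- tp + y[i]
    r <- tp / npos
    s <- s + (r - prev_r) * (tp / i)
    prev_r <- r
  }
  s
}

# exhaustive per-sample top-k check
oracle_topk <- function(scores, y, k) {
  hits <- c()
  for (i in seq_len(nrow(y))) {
    if (sum(y[i, ]) == 0) next
    top <- order(-scores[i, ])[seq_len(k)]
    hits <- c(hits, any(y[i, top] == 1))
  }
  mean(hits)
}

# tiny architectures used across training-oriented tests
tiny_model_config <- function(L = 12L, C = 2L, fc = 6L) {
  model_config(input_length = L, n_classes = C, D = 6L, i = 3L, n_heads = 1L,
               kernel_sizes = c(3L, 3L, 5L), d_v = 1L, n_layers = 2L,
               pool_after = 1L, pool_size = 2L, pool_stride = 2L,
               fc_hidden = fc, dropout_feature = 0, dropout_fc = 0)
}

tiny_dataset <- function(n = 24L, L = 12L, C = 2L, seed = 5L) {
  pwms <- make_default_pwms(C = C, m = 4L, sharpness = 8, seed = seed)
  sim <- simulate_dataset(sim_config(n = n, length = L, pwms = pwms,
                                     prevalence = 0.4, seed = seed))
  as_cac_dataset(sim, split_frac = 0.75, split_seed = seed)
}
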