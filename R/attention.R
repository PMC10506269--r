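#' Row-wise softmax
#'
#' Numerically stable softmax applied independently to each row (the maximum
#' of the row is subtracted before exponentiation), as used to normalise the
#' scaled dot-product attention scores.
#'
#' @param m numeric matrix with finite entries.
#' @return matrix of the same shape; every row sums to 1, entries in (0, 1].
#' @export
softmax_rows <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stopf("m must be a numeric matrix")
  if (!all(is.finite(m))) stopf("softmax_rows requires finite entries")
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

#' Projection weights of one attention head
#'
#' Holds the query/key/value projections `W_Q` (D x d_k), `W_K` (D x d_k) and
#' `W_V` (D x d_h) of a single scaled dot-product attention head acting on an
#' L x D feature map. Projections are pure matrix products (no bias).
#'
#' @param W_q,W_k query/key projection matrices, D x d_k.
#' @param W_v value projection matrix, D x d_h.
#' @return an `attention_head_params` object.
#' @export
attention_head_params <- function(W_q, W_k, W_v) {
  for (w in list(W_q, W_k, W_v)) {
    if (!is.matrix(w) || !is.numeric(w)) stopf("projections must be numeric matrices")
  }
  if (nrow(W_q) != nrow(W_k) || nrow(W_q) != nrow(W_v)) {
    stopf("projections disagree on input width D: %d / %d / %d",
          nrow(W_q), nrow(W_k), nrow(W_v))
  }
  if (ncol(W_q) != ncol(W_k)) {
    stopf("W_Q and W_K must share d_k (got %d and %d)", ncol(W_q), ncol(W_k))
  }
  if (ncol(W_q) < 1L || ncol(W_v) < 1L) stopf("d_k and d_h must be >= 1")
  structure(list(W_q = W_q, W_k = W_k, W_v = W_v), class = "attention_head_params")
}

#' Attention weight matrix of one head
#'
#' Returns the L x L row-stochastic matrix
#' `Softmax((X W_Q)(X W_K)^T / sqrt(d_k))` whose row t gives the mixing
#' weights that position t places on every position of the input.
#'
#' @param X L x D feature map.
#' @param p an [attention_head_params()].
#' @return L x L matrix with non-negative rows summing to 1.
#' @export
attention_weights <- function(X, p) {
  check_feature_map(X, nrow(p$W_q))
  q <- X %*% p$W_q
  k <- X %*% p$W_k
  softmax_rows(tcrossprod(q, k) / sqrt(ncol(p$W_q)))
}

check_feature_map <- function(X, D_expect = NULL) {
  if (!is.matrix(X) || !is.numeric(X)) stopf("feature map must be a numeric matrix")
  if (!all(is.finite(X))) stopf("feature map contains non-finite entries")
  if (!is.null(D_expect) && ncol(X) != D_expect) {
    stopf("feature map is %d x %d but parameters expect %d input channels",
          nrow(X), ncol(X), D_expect)
  }
  invisible(X)
}

#' Single-head scaled dot-product self-attention
#'
#' Computes `Softmax((X W_Q)(X W_K)^T / sqrt(d_k)) (X W_V)`: queries, keys and
#' values all derive from the same input, scores are scaled by `1/sqrt(d_k)`,
#' and the output at each position is a convex combination of the value rows.
#' There is no positional encoding; the operator is equivariant under
#' permutation of the L positions.
#'
#' @param X L x D feature map.
#' @param p an [attention_head_params()].
#' @return L x d_h matrix.
#' @export
single_head_attention <- function(X, p) {
  stopifnot(inherits(p, "attention_head_params"))
  check_feature_map(X, nrow(p$W_q))
  attention_weights(X, p) %*% (X %*% p$W_v)
}

#' Multi-head attention parameters
#'
#' `N_h` heads sharing the geometry `(d_k, d_h)` plus the output projection
#' `W^o` (d_V x d_V with `d_V = N_h * d_h`) applied to the channel-wise
#' concatenation of the head outputs.
#'
#' @param heads list of [attention_head_params()], all with equal `d_k`, `d_h`
#'   and input width.
#' @param W_o output projection, d_V x d_V.
#' @return an `mha_params` object.
#' @export
mha_params <- function(heads, W_o) {
  if (!length(heads)) stopf("need at least one head")
  lapply(heads, function(h) stopifnot(inherits(h, "attention_head_params")))
  dks <- vapply(heads, function(h) ncol(h$W_q), integer(1L))
  dhs <- vapply(heads, function(h) ncol(h$W_v), integer(1L))
  Ds  <- vapply(heads, function(h) nrow(h$W_q), integer(1L))
  if (length(unique(dks)) != 1L || length(unique(dhs)) != 1L || length(unique(Ds)) != 1L) {
    stopf("heads disagree on geometry: d_k {%s}, d_h {%s}, D {%s}",
          paste(unique(dks), collapse = ","), paste(unique(dhs), collapse = ","),
          paste(unique(Ds), collapse = ","))
  }
  d_v <- length(heads) * dhs[1L]
  if (!is.matrix(W_o) || nrow(W_o) != d_v || ncol(W_o) != d_v) {
    stopf("W_o must be %d x %d (d_V = N_h * d_h), got %d x %d",
          d_v, d_v, NROW(W_o), NCOL(W_o))
  }
  structure(
    list(heads = heads, W_o = W_o, n_heads = length(heads),
         d_k = dks[1L], d_h = dhs[1L], d_v = d_v, D = Ds[1L]),
    class = "mha_params"
  )
}

#' Multi-head self-attention
#'
#' Runs every head on the same input, concatenates the head outputs along
#' channels and applies the learned output projection `W^o`; the result is
#' asserted to have the target shape L x d_V (the final "reshape" is a shape
#' check — concatenation and projection already produce the target dimension).
#'
#' @param X L x D feature map.
#' @param p an [mha_params()].
#' @return L x d_V matrix.
#' @export
multi_head_attention <- function(X, p) {
  stopifnot(inherits(p, "mha_params"))
  check_feature_map(X, p$D)
  H <- do.call(cbind, lapply(p$heads, function(h) single_head_attention(X, h)))
  out <- H %*% p$W_o
  stopifnot(nrow(out) == nrow(X), ncol(out) == p$d_v)
  out
}

#' Randomly initialised multi-head attention parameters
#'
#' Glorot-uniform projections drawn from the current RNG stream (wrap in
#' [with_seed()] or `set.seed()` for reproducibility).
#'
#' @param D input channel count.
#' @param n_heads number of heads.
#' @param d_k key/query width per head.
#' @param d_h value width per head; defaults to `d_k`.
#' @return an [mha_params()].
#' @export
random_mha_params <- function(D, n_heads, d_k, d_h = d_k) {
  heads <- lapply(seq_len(n_heads), function(i) {
    attention_head_params(
      glorot_uniform(D, d_k),
      glorot_uniform(D, d_k),
      glorot_uniform(D, d_h)
    )
  })
  d_v <- n_heads * d_h
  mha_params(heads, glorot_uniform(d_v, d_v))
}

# --- fused <-> per-head conversions used by the network engine -------------
# The engine stores one fused matrix per projection (columns blocked by head);
# these helpers translate to/from the user-facing per-head representation.

fuse_mha_params <- function(p) {
  stopifnot(inherits(p, "mha_params"))
  list(
    Wq = do.call(cbind, lapply(p$heads, function(h) h$W_q)),
    Wk = do.call(cbind, lapply(p$heads, function(h) h$W_k)),
    Wv = do.call(cbind, lapply(p$heads, function(h) h$W_v)),
    Wo = p$W_o
  )
}

split_mha_params <- function(att, n_heads, d_k, d_h) {
  heads <- lapply(seq_len(n_heads), function(h) {
    qc <- ((h - 1L) * d_k + 1L):(h * d_k)
    vc <- ((h - 1L) * d_h + 1L):(h * d_h)
    attention_head_params(
      att$Wq[, qc, drop = FALSE],
      att$Wk[, qc, drop = FALSE],
      att$Wv[, vc, drop = FALSE]
    )
  })
  mha_params(heads, att$Wo)
}
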