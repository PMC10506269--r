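#' Attention-augmented convolution branch configuration
#'
#' Channel accounting of one branch: the `d_out` output channels are the
#' concatenation of `d_conv = d_out - d_v` ordinary convolution channels and
#' `d_v` multi-head self-attention channels. `d_v` must be a positive multiple
#' of `n_heads` and strictly smaller than `d_out`. The default attention
#' fraction is `d_out / 4`, rounded down to a multiple of `n_heads` (but at
#' least one head-width), keeping the convolution branch dominant.
#'
#' @param d_out total output channels of the branch.
#' @param kernel_size odd convolution kernel width.
#' @param n_heads attention heads.
#' @param input_channels channels of the incoming feature map.
#' @param d_v attention channels; `NULL` for the default rule.
#' @return an `aa_conv_config` with fields `d_out`, `d_v`, `d_conv`,
#'   `kernel_size`, `n_heads`, `d_k`, `d_h`, `input_channels`.
#' @export
aa_conv_config <- function(d_out, kernel_size, n_heads, input_channels, d_v = NULL) {
  if (!is_count(d_out) || !is_count(kernel_size) || !is_count(n_heads) ||
      !is_count(input_channels)) {
    stopf("d_out, kernel_size, n_heads and input_channels must be positive integers")
  }
  if (kernel_size %% 2L == 0L) stopf("kernel_size must be odd, got %d", kernel_size)
  if (is.null(d_v)) {
    d_v <- max(n_heads, (d_out %/% 4L) %/% n_heads * n_heads)
  }
  if (!is_count(d_v) || d_v %% n_heads != 0L) {
    stopf("d_v must be a positive multiple of n_heads (d_v = %s, n_heads = %d)",
          format(d_v), n_heads)
  }
  d_conv <- d_out - d_v
  if (d_v >= d_out || d_conv < 1L) {
    stopf("channel accounting violated: d_out = %d, d_v = %d leaves d_conv = %d (need 0 < d_v < d_out)",
          d_out, d_v, d_conv)
  }
  d_h <- d_v %/% n_heads
  structure(
    list(d_out = as.integer(d_out), d_v = as.integer(d_v), d_conv = as.integer(d_conv),
         kernel_size = as.integer(kernel_size), n_heads = as.integer(n_heads),
         d_k = as.integer(d_h), d_h = as.integer(d_h),
         input_channels = as.integer(input_channels)),
    class = "aa_conv_config"
  )
}

#' Parallel concatenated attention-augmented convolution layer configuration
#'
#' One feature layer = `i` attention-augmented convolution branches applied in
#' parallel to the same input, each activated and concatenated along channels.
#' The `D` output channels are divided equally, `d_out = D / i` per branch.
#' Branches differ only in kernel size (multi-scale motif detection; defaults
#' 7/11/19).
#'
#' @param D total output channels; must be divisible by `i`.
#' @param input_channels channels of the incoming feature map.
#' @param i number of parallel branches.
#' @param kernel_sizes odd kernel widths, recycled to length `i`.
#' @param n_heads heads per branch.
#' @param d_v attention channels per branch (`NULL` = default rule).
#' @param activation branch nonlinearity tag (default `"relu"`).
#' @return a `cac_layer_config` with a `branches` list of [aa_conv_config()].
#' @export
cac_layer_config <- function(D, input_channels, i = 3L, kernel_sizes = c(7L, 11L, 19L),
                             n_heads = 8L, d_v = NULL, activation = "relu") {
  if (!is_count(D) || !is_count(i)) stopf("D and i must be positive integers")
  if (D %% i != 0L) stopf("D = %d is not divisible by branch count i = %d", D, i)
  ks <- rep_len(as.integer(kernel_sizes), i)
  branches <- lapply(ks, function(k) {
    aa_conv_config(d_out = D %/% i, kernel_size = k, n_heads = n_heads,
                   input_channels = input_channels, d_v = d_v)
  })
  activation_fun(activation)  # validate tag
  structure(
    list(D = as.integer(D), i = as.integer(i), branches = branches,
         activation = activation, input_channels = as.integer(input_channels)),
    class = "cac_layer_config"
  )
}

#' Max-pooling configuration
#' @param size window size (default 4).
#' @param stride step between windows (default 4).
#' @return a `pool_config`.
#' @export
pool_config <- function(size = 4L, stride = 4L) {
  if (!is_count(size) || !is_count(stride)) stopf("size and stride must be positive integers")
  structure(list(size = as.integer(size), stride = as.integer(stride)), class = "pool_config")
}

pooled_length <- function(L, cfg) as.integer((L - cfg$size) %/% cfg$stride + 1L)

# kernel array (k, D_in, d_conv) <-> im2col weight matrix (k*D_in, d_conv)
# with row order (offset j, channel c) -> (j-1)*D_in + c.
kernel_array_to_mat <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

kernel_mat_to_array <- function(W, k, D_in) {
  aperm(array(W, c(D_in, k, ncol(W))), c(2L, 1L, 3L))
}

#' 1D convolution with "same" zero padding
#'
#' Stride-1 cross-correlation over the length axis with `(k-1)/2` zeros padded
#' on each side, so the output length equals the input length (required for
#' the position-wise concatenation with the attention channels).
#'
#' @param X L x D_in feature map.
#' @param kernels weight array of dim `(kernel_size, D_in, d_conv)`.
#' @param bias numeric vector of length `d_conv`.
#' @return L x d_conv matrix.
#' @export
conv1d_same <- function(X, kernels, bias = NULL) {
  check_feature_map(X)
  if (!is.array(kernels) || length(dim(kernels)) != 3L) {
    stopf("kernels must be a (kernel_size, D_in, d_conv) array")
  }
  k <- dim(kernels)[1L]
  if (k %% 2L == 0L) stopf("kernel_size must be odd, got %d", k)
  if (dim(kernels)[2L] != ncol(X)) {
    stopf("kernels expect %d input channels, feature map has %d", dim(kernels)[2L], ncol(X))
  }
  d_conv <- dim(kernels)[3L]
  if (is.null(bias)) bias <- numeric(d_conv)
  if (length(bias) != d_conv) stopf("bias length %d != %d filters", length(bias), d_conv)
  out <- conv_fwd_batch(X, kernel_array_to_mat(kernels), bias, k, nrow(X), 1L)$Y
  matrix(out, nrow(X), d_conv)
}

#' Attention-augmented convolution
#'
#' One branch forward pass: the channel-wise concatenation
#' `[Conv(X) | MHA(X)]` of a same-padded 1D convolution (`d_conv` filters)
#' and multi-head self-attention (`d_v` channels) applied to the same input.
#'
#' @param X L x D_in feature map.
#' @param cfg an [aa_conv_config()].
#' @param conv_params list with `kernels` (array `(k, D_in, d_conv)`) and
#'   `bias` (length `d_conv`).
#' @param mha_params an [mha_params()] producing `d_v` channels.
#' @return L x d_out matrix.
#' @export
attention_augmented_conv <- function(X, cfg, conv_params, mha_params) {
  stopifnot(inherits(cfg, "aa_conv_config"))
  check_feature_map(X, cfg$input_channels)
  if (mha_params$d_v != cfg$d_v) {
    stopf("channel accounting violated: config has d_out = %d, d_v = %d, d_conv = %d but attention emits %d channels",
          cfg$d_out, cfg$d_v, cfg$d_conv, mha_params$d_v)
  }
  if (dim(conv_params$kernels)[3L] != cfg$d_conv) {
    stopf("channel accounting violated: config has d_out = %d, d_v = %d, d_conv = %d but convolution has %d filters",
          cfg$d_out, cfg$d_v, cfg$d_conv, dim(conv_params$kernels)[3L])
  }
  out <- cbind(
    conv1d_same(X, conv_params$kernels, conv_params$bias),
    multi_head_attention(X, mha_params)
  )
  stopifnot(ncol(out) == cfg$d_out)
  out
}

#' Concatenated attention-augmented convolution layer
#'
#' Applies every branch to the *same* input, passes each branch output through
#' the layer activation, and concatenates along channels:
#' `H(X) = Concat[sigma(branch_1(X)), ..., sigma(branch_i(X))]`.
#'
#' @param X L x D_in feature map.
#' @param cfg a [cac_layer_config()].
#' @param params list of length `i`; element j holds `conv` (list `kernels`,
#'   `bias`) and `mha` (an [mha_params()]) for branch j.
#' @return L x D feature map.
#' @export
cac_layer_forward <- function(X, cfg, params) {
  stopifnot(inherits(cfg, "cac_layer_config"))
  if (length(params) != cfg$i) stopf("expected %d branch parameter sets, got %d", cfg$i, length(params))
  act <- activation_fun(cfg$activation)
  outs <- lapply(seq_len(cfg$i), function(j) {
    act(attention_augmented_conv(X, cfg$branches[[j]], params[[j]]$conv, params[[j]]$mha))
  })
  H <- do.call(cbind, outs)
  stopifnot(ncol(H) == cfg$D, nrow(H) == nrow(X))  # channel conservation
  H
}

#' Max pooling over the length axis
#'
#' Channel-wise window maxima; output length is
#' `floor((L - size) / stride) + 1`.
#'
#' @param X L x D feature map.
#' @param cfg a [pool_config()].
#' @return matrix of pooled features.
#' @export
max_pool <- function(X, cfg = pool_config()) {
  check_feature_map(X)
  stopifnot(inherits(cfg, "pool_config"))
  if (nrow(X) < cfg$size) {
    stopf("input length %d is shorter than the pooling window %d", nrow(X), cfg$size)
  }
  pool_fwd_batch(X, cfg$size, cfg$stride, nrow(X), 1L)$Y
}

#' Randomly initialised parameters for one branch
#'
#' @param cfg an [aa_conv_config()].
#' @return list with `conv` (kernels, bias) and `mha`; draws from the current
#'   RNG stream.
#' @export
random_branch_params <- function(cfg) {
  stopifnot(inherits(cfg, "aa_conv_config"))
  k <- cfg$kernel_size
  W <- glorot_uniform(k * cfg$input_channels, cfg$d_conv)
  list(
    conv = list(kernels = kernel_mat_to_array(W, k, cfg$input_channels),
                bias = numeric(cfg$d_conv)),
    mha = random_mha_params(cfg$input_channels, cfg$n_heads, cfg$d_k, cfg$d_h)
  )
}
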