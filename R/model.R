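#' Network configuration
#'
#' Defaults mirror the reference architecture for 1000-nt transcription-factor
#' windows: three concatenated attention-augmented convolution layers
#' (D = 192 channels each, i = 3 parallel branches, 8 heads), max pooling
#' (size 4, stride 4) after layers 1 and 2, then flatten, dropout 0.2, one
#' hidden fully connected layer (512, ReLU), dropout 0.5, and a sigmoid
#' output head with one unit per class.
#'
#' @param input_length sequence length L.
#' @param n_classes number of classes C.
#' @param D channels per feature layer (divisible by `i`).
#' @param i parallel branches per layer.
#' @param n_heads attention heads per branch.
#' @param kernel_sizes odd kernel widths for the `i` branches.
#' @param d_v attention channels per branch (`NULL` = `d_out/4` rounded down
#'   to a multiple of `n_heads`).
#' @param n_layers number of feature layers.
#' @param pool_after indices of layers followed by max pooling; `NULL` places
#'   a pool after every layer except the last (the default c(1, 2) at three
#'   layers).
#' @param pool_size,pool_stride pooling geometry.
#' @param fc_hidden width of the hidden fully connected layer.
#' @param dropout_feature dropout rate after flattening the feature stack.
#' @param dropout_fc dropout rate after the hidden FC layer.
#' @return a `model_config` object.
#' @export
model_config <- function(input_length, n_classes, D = 192L, i = 3L, n_heads = 8L,
                         kernel_sizes = c(7L, 11L, 19L), d_v = NULL, n_layers = 3L,
                         pool_after = NULL, pool_size = 4L, pool_stride = 4L,
                         fc_hidden = 512L, dropout_feature = 0.2, dropout_fc = 0.5) {
  if (!is_count(input_length) || !is_count(n_classes)) {
    stopf("input_length and n_classes must be positive integers")
  }
  if (is.null(pool_after)) pool_after <- seq_len(max(n_layers - 1L, 0L))
  if (any(pool_after > n_layers)) stopf("pool_after refers past the last layer")
  for (dr in c(dropout_feature, dropout_fc)) {
    if (!is.numeric(dr) || dr < 0 || dr >= 1) stopf("dropout rates must lie in [0, 1)")
  }
  layers <- vector("list", n_layers)
  d_in <- 4L
  for (l in seq_len(n_layers)) {
    layers[[l]] <- cac_layer_config(D = D, input_channels = d_in, i = i,
                                    kernel_sizes = kernel_sizes, n_heads = n_heads,
                                    d_v = d_v)
    d_in <- as.integer(D)
  }
  cfg <- structure(
    list(input_length = as.integer(input_length), n_classes = as.integer(n_classes),
         layers = layers, pool_after = as.integer(pool_after),
         pool = pool_config(pool_size, pool_stride),
         fc_hidden = as.integer(fc_hidden),
         dropout_feature = dropout_feature, dropout_fc = dropout_fc),
    class = "model_config"
  )
  model_dims(cfg)  # validates that pooling never underruns the length
  cfg
}

#' Per-stage lengths and flattened width of a configuration
#'
#' @param cfg a [model_config()].
#' @return list with `stage_lengths` (length after each feature stage,
#'   starting from the input) and `flat_width` (length * channels entering the
#'   classifier).
#' @export
model_dims <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  L <- cfg$input_length
  lens <- L
  for (l in seq_along(cfg$layers)) {
    if (l %in% cfg$pool_after) {
      if (L < cfg$pool$size) stopf("length %d underruns pooling window after layer %d", L, l)
      L <- pooled_length(L, cfg$pool)
    }
    lens <- c(lens, L)
  }
  list(stage_lengths = as.integer(lens),
       flat_width = as.integer(L * cfg$layers[[length(cfg$layers)]]$D))
}

#' Build a network with deterministic initial weights
#'
#' Glorot-uniform weights, zero biases; the same `(cfg, seed)` pair always
#' yields bitwise-identical parameters.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the initialisation.
#' @return a `cac_model` (list with `config`, `params`, `seed`).
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  dims <- model_dims(cfg)
  params <- with_seed(seed, {
    layers <- lapply(cfg$layers, function(lc) {
      lapply(lc$branches, function(bc) {
        list(
          conv = list(W = glorot_uniform(bc$kernel_size * bc$input_channels, bc$d_conv),
                      b = numeric(bc$d_conv)),
          att = list(
            Wq = glorot_uniform(bc$input_channels, bc$n_heads * bc$d_k),
            Wk = glorot_uniform(bc$input_channels, bc$n_heads * bc$d_k),
            Wv = glorot_uniform(bc$input_channels, bc$n_heads * bc$d_h),
            Wo = glorot_uniform(bc$d_v, bc$d_v)
          )
        )
      })
    })
    list(
      layers = layers,
      fc = list(W1 = glorot_uniform(dims$flat_width, cfg$fc_hidden),
                b1 = numeric(cfg$fc_hidden),
                W2 = glorot_uniform(cfg$fc_hidden, cfg$n_classes),
                b2 = numeric(cfg$n_classes))
    )
  })
  structure(list(config = cfg, params = params, seed = as.integer(seed)),
            class = "cac_model")
}

#' @export
print.cac_model <- function(x, ...) {
  d <- model_dims(x$config)
  cat(sprintf(
    "<cac_model: %d feature layers (D = %s), input %d nt, %d classes, %s parameters>\n",
    length(x$config$layers),
    paste(vapply(x$config$layers, `[[`, integer(1L), "D"), collapse = "/"),
    x$config$input_length, x$config$n_classes,
    format(count_parameters(x), big.mark = ",")
  ))
  cat(sprintf("  stage lengths: %s; flattened width: %d\n",
              paste(d$stage_lengths, collapse = " -> "), d$flat_width))
  invisible(x)
}

#' Predicted class probabilities
#'
#' Inference-mode forward pass (dropout disabled, deterministic).
#'
#' @param object a `cac_model`.
#' @param newdata a [cac_dataset()] or a one-hot array `(L, 4, n)`.
#' @param batch_size samples per forward chunk.
#' @param ... unused.
#' @return n x C matrix of probabilities in (0, 1).
#' @export
predict.cac_model <- function(object, newdata, batch_size = 128L, ...) {
  x <- if (inherits(newdata, "cac_dataset")) newdata$x else newdata
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (dim(x)[1L] != object$config$input_length || dim(x)[2L] != 4L) {
    stopf("input is %d x %d, model expects %d x 4", dim(x)[1L], dim(x)[2L],
          object$config$input_length)
  }
  n <- dim(x)[3L]
  out <- matrix(0, n, object$config$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    out[idx, ] <- engine_forward(object, x[, , idx, drop = FALSE])$prob
  }
  out
}

#' Multi-label binary cross-entropy
#'
#' The training objective: `zeta = -sum_cells [ y log p + (1 - y) log(1 - p) ]`
#' with probabilities clamped to `[1e-12, 1 - 1e-12]` before the logarithms.
#' Non-negative, and zero (up to clamping) iff predictions equal labels.
#'
#' @param pred n x C matrix of probabilities.
#' @param y n x C 0/1 matrix or [label_matrix()].
#' @return scalar loss.
#' @export
bce_loss <- function(pred, y) {
  y <- label_values(y)
  pred <- as.matrix(pred)
  if (!all(dim(pred) == dim(y))) {
    stopf("prediction is %d x %d but labels are %d x %d",
          nrow(pred), ncol(pred), nrow(y), ncol(y))
  }
  p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Number of trainable parameters
#'
#' `count_parameters` introspects the weight tree of a built model;
#' [parameter_count_formula()] evaluates the closed form from the
#' configuration alone. The two agree exactly for every valid configuration.
#'
#' @param model a `cac_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cac_model"))
  sum(rapply(model$params, length, how = "unlist"))
}

#' @rdname count_parameters
#' @param cfg a [model_config()].
#' @export
parameter_count_formula <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  total <- 0L
  for (lc in cfg$layers) {
    for (bc in lc$branches) {
      conv <- bc$kernel_size * bc$input_channels * bc$d_conv + bc$d_conv
      d_k_total <- bc$n_heads * bc$d_k
      att <- bc$input_channels * (2L * d_k_total + bc$d_v) + bc$d_v^2
      total <- total + conv + att
    }
  }
  d <- model_dims(cfg)
  total <- total +
    d$flat_width * cfg$fc_hidden + cfg$fc_hidden +      # hidden FC
    cfg$fc_hidden * cfg$n_classes + cfg$n_classes       # output head
  as.integer(total)
}

#' Reference-form parameters of one branch of a built model
#'
#' Exposes the engine's fused weights of layer `layer`, branch `branch` in the
#' user-facing form consumed by [attention_augmented_conv()] /
#' [cac_layer_forward()]: a `conv` list (`kernels` array, `bias`) and an
#' [mha_params()].
#'
#' @param model a `cac_model`.
#' @param layer,branch 1-based indices.
#' @return list with elements `conv` and `mha`.
#' @export
model_branch_params <- function(model, layer, branch) {
  stopifnot(inherits(model, "cac_model"))
  bc <- model$config$layers[[layer]]$branches[[branch]]
  bp <- model$params$layers[[layer]][[branch]]
  list(
    conv = list(kernels = kernel_mat_to_array(bp$conv$W, bc$kernel_size, bc$input_channels),
                bias = bp$conv$b),
    mha = split_mha_params(bp$att, bc$n_heads, bc$d_k, bc$d_h)
  )
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the weights, the full configuration, the build seed and
#' (optionally) a training history, so any evaluation is reproducible.
#'
#' @param model a `cac_model`.
#' @param path file path (RDS).
#' @param history optional training history to store alongside.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint` a
#'   list with `model` and `history`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  stopifnot(inherits(model, "cac_model"))
  saveRDS(list(model = model, history = history, package_version = "0.1.0"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: '%s'", path)
  x <- readRDS(path)
  if (!is.list(x) || !inherits(x$model, "cac_model")) {
    stopf("'%s' is not a model checkpoint", path)
  }
  x
}
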