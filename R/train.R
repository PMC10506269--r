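#' Training configuration
#'
#' SGD with momentum, mini-batches, and early stopping that monitors
#' validation accuracy: training halts once the monitor has not improved
#' (strictly) for `patience` consecutive epochs, or at `max_epochs`, and the
#' weights from the best epoch are restored. Defaults follow the reference
#' protocol (max 200 epochs, patience 20, pooled SGD); learning rate and
#' momentum are not stated there and default to 0.01 / 0.9.
#'
#' @param learning_rate SGD step size (> 0).
#' @param momentum classical momentum coefficient in [0, 1).
#' @param batch_size mini-batch size.
#' @param max_epochs hard cap on epochs.
#' @param patience epochs without improvement before stopping; must be smaller
#'   than `max_epochs`.
#' @param seed seed controlling shuffling and dropout.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9, batch_size = 64L,
                         max_epochs = 200L, patience = 20L, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) stopf("learning_rate must be > 0")
  if (!is.numeric(momentum) || momentum < 0 || momentum >= 1) stopf("momentum must lie in [0, 1)")
  if (!is_count(batch_size) || !is_count(max_epochs) || !is_count(patience)) {
    stopf("batch_size, max_epochs and patience must be positive integers")
  }
  if (patience >= max_epochs) stopf("patience (%d) must be smaller than max_epochs (%d)",
                                    patience, max_epochs)
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Top-1 accuracy used as the per-epoch monitor
#'
#' Defined as [top_k_accuracy()] with `k = 1`; samples without any true label
#' are excluded from the denominator (silently here — this runs every epoch).
#'
#' @param scores n x C score matrix.
#' @param y labels.
#' @return fraction in [0, 1].
#' @export
epoch_accuracy <- function(scores, y) {
  top_k_accuracy(scores, y, k = 1L, warn = FALSE)
}

# zero-filled tree with the same shape as a parameter tree
zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

sgd_update <- function(params, grads, vel, lr, mom) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)   # match by name where trees are named
      out_p <- p; out_v <- v
      for (nm in keys) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p
        out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      v_new <- mom * v - lr * g
      list(p = p + v_new, v = v_new)
    }
  }
  walk(params, grads, vel)
}

#' Train a network with SGD and validation-accuracy early stopping
#'
#' Mini-batch SGD with momentum on the mean per-sample binary cross-entropy.
#' After every epoch the monitor (validation top-1 accuracy by default) is
#' evaluated in inference mode; a strict improvement checkpoints the weights,
#' and `patience` consecutive epochs without improvement stop the run. The
#' returned model carries the best-epoch weights, not the last ones.
#'
#' @param model a freshly built (or warm) `cac_model`.
#' @param train_data,val_data lists with `x` (one-hot array `(L, 4, n)`) and
#'   `y` (n x C label matrix), e.g. from [dataset_tensors()].
#' @param cfg a [train_config()].
#' @param monitor_fn optional override of the monitor: a
#'   `function(model, val_data, epoch)` returning a scalar (larger is better).
#'   Used mainly to test the stopping semantics.
#' @param verbose print one line per epoch.
#' @return list with `model` (best checkpoint), `history` (per-epoch
#'   data.frame: `epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`,
#'   `monitor`), `best_epoch`, `stopped_epoch`, `best_monitor`.
#' @export
train_network <- function(model, train_data, val_data, cfg = train_config(),
                          monitor_fn = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cac_model"), inherits(cfg, "train_config"))
  n_tr <- dim(train_data$x)[3L]
  n_va <- if (is.null(val_data)) 0L else dim(val_data$x)[3L]
  if (n_tr < 1L) stopf("training set is empty")
  if (n_va < 1L) stopf("validation set is empty: the early-stopping monitor is undefined")
  if (nrow(train_data$y) != n_tr) stopf("training labels/tensor size mismatch")
  C <- model$config$n_classes
  if (ncol(train_data$y) != C) stopf("labels have %d classes, model expects %d",
                                     ncol(train_data$y), C)

  vel <- zeros_like(model$params)
  hist <- vector("list", cfg$max_epochs)
  best <- -Inf; best_epoch <- 0L; best_params <- model$params
  wait <- 0L; stopped <- cfg$max_epochs

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; tr_scores <- matrix(0, n_tr, C)
      for (s in seq(1L, n_tr, by = cfg$batch_size)) {
        idx <- ord[s:min(n_tr, s + cfg$batch_size - 1L)]
        xb <- train_data$x[, , idx, drop = FALSE]
        yb <- train_data$y[idx, , drop = FALSE]
        fw <- engine_forward(model, xb, training = TRUE, cache = TRUE)
        ep_loss <- ep_loss + bce_loss(fw$prob, yb)
        tr_scores[idx, ] <- fw$prob
        dlogits <- (fw$prob - yb) / length(idx)   # mean-per-sample BCE gradient
        g <- engine_backward(model, xb, fw$cache, dlogits)
        g$dX <- NULL
        upd <- sgd_update(model$params, g, vel, cfg$learning_rate, cfg$momentum)
        model$params <- upd$p
        vel <- upd$v
      }
      if (!is.finite(ep_loss)) {
        stopf("training diverged at epoch %d (non-finite loss); reduce the learning rate", epoch)
      }
      train_loss <- ep_loss / n_tr
      train_acc <- epoch_accuracy(tr_scores, train_data$y)
      val_prob <- predict(model, val_data$x)
      val_loss <- bce_loss(val_prob, val_data$y) / n_va
      val_acc <- epoch_accuracy(val_prob, val_data$y)
      monitor <- if (is.null(monitor_fn)) val_acc else monitor_fn(model, val_data, epoch)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  train_acc = train_acc, val_loss = val_loss,
                                  val_acc = val_acc, monitor = monitor)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                        epoch, train_loss, train_acc, val_loss, val_acc))
      }
      if (monitor > best) {            # strict improvement resets patience
        best <- monitor; best_epoch <- epoch
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) { stopped <- epoch; break }
      }
    }
  })

  model$params <- best_params
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1L))])
  list(model = model, history = history, best_epoch = best_epoch,
       stopped_epoch = min(stopped, nrow(history)), best_monitor = best)
}
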