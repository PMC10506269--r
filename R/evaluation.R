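#' Multi-label top-k accuracy
#'
#' Fraction of samples whose k highest-scored classes include at least one
#' true label. Ties in the scores are broken deterministically towards the
#' lowest class index. Samples without any true label are excluded from the
#' denominator (with a warning unless `warn = FALSE`).
#'
#' @param scores n x C score matrix.
#' @param y n x C 0/1 labels or [label_matrix()].
#' @param k number of top predictions considered, `1 <= k <= C`.
#' @param warn warn when unlabeled samples are dropped.
#' @return fraction in [0, 1].
#' @export
top_k_accuracy <- function(scores, y, k, warn = TRUE) {
  y <- label_values(y)
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(y))) stopf("scores and labels disagree on shape")
  C <- ncol(y)
  if (!is_count(k) || k > C) stopf("k must satisfy 1 <= k <= C = %d", C)
  has_label <- rowSums(y) > 0
  if (!all(has_label) && warn) {
    warnf("%d sample(s) carry no true label and are excluded from top-%d accuracy",
          sum(!has_label), k)
  }
  if (!any(has_label)) stopf("no labelled samples: top-k accuracy undefined")
  hits <- vapply(which(has_label), function(i) {
    top <- order(-scores[i, ])[seq_len(k)]   # stable: ties -> lowest class index
    any(y[i, top] == 1)
  }, logical(1L))
  mean(hits)
}

#' Area under the ROC curve
#'
#' Computed through the exactly equivalent rank (Mann-Whitney) formulation
#' with mid-ranks, i.e. `P(score_pos > score_neg) + 0.5 P(tie)`; invariant
#' under strictly monotone transforms of the scores and numerically robust.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector of the same length; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("ROC AUC undefined: need both classes (%d positive, %d negative)", n_pos, n_neg)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision
#'
#' `AP = sum_k (R_k - R_{k-1}) P_k` over the list sorted by decreasing score
#' (step-wise, no interpolation); score ties are ordered deterministically by
#' original index.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector; at least one positive required.
#' @return AP in [0, 1].
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stopf("average precision undefined without positives")
  ord <- order(-scores, seq_along(scores))
  yl <- labels[ord]
  tp <- cumsum(yl)
  prec <- tp / seq_along(yl)
  sum(prec[yl == 1]) / n_pos
}

# FPR/TPR points of the empirical ROC curve (threshold sweep, ties merged).
roc_points <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  yl <- as.numeric(labels)[ord]; sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE)     # last point of each tie group
  tp <- cumsum(yl)[keep]; fp <- cumsum(1 - yl)[keep]
  data.frame(fpr = c(0, fp / max(sum(labels == 0), 1)),
             tpr = c(0, tp / max(sum(labels == 1), 1)))
}

pr_points <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  yl <- as.numeric(labels)[ord]
  tp <- cumsum(yl)
  data.frame(recall = tp / max(sum(yl), 1), precision = tp / seq_along(yl))
}

#' Build a multi-label evaluation report
#'
#' Per-class ROC AUC and average precision, macro (unweighted mean over
#' classes where the metric is defined) and micro (metrics on the flattened
#' score/label vectors) aggregates, top-1/top-3 accuracy, and the per-class
#' ROC / precision-recall curve points. Classes where a metric is undefined
#' (single-class labels) are reported as `NA` and flagged, never silently
#' dropped.
#'
#' @param scores n x C score matrix.
#' @param y labels ([label_matrix()] or 0/1 matrix).
#' @param class_names optional class names (defaults to those in `y`).
#' @return a `cac_eval_report`.
#' @export
build_report <- function(scores, y, class_names = NULL) {
  yv <- label_values(y)
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(yv))) stopf("scores and labels disagree on shape")
  C <- ncol(yv)
  if (is.null(class_names)) {
    class_names <- if (inherits(y, "label_matrix")) y$class_names else paste0("class", seq_len(C))
  }
  auc <- ap <- rep(NA_real_, C)
  undefined <- character(0)
  roc_list <- pr_list <- stats::setNames(vector("list", C), class_names)
  for (j in seq_len(C)) {
    lab <- yv[, j]
    if (length(unique(lab)) == 2L) {
      auc[j] <- roc_auc(scores[, j], lab)
      roc_list[[j]] <- roc_points(scores[, j], lab)
    }
    if (sum(lab) >= 1L) {
      ap[j] <- average_precision(scores[, j], lab)
      pr_list[[j]] <- pr_points(scores[, j], lab)
    }
    if (is.na(auc[j]) || is.na(ap[j])) undefined <- c(undefined, class_names[j])
  }
  flat_s <- as.vector(scores); flat_y <- as.vector(yv)
  micro_auc <- if (length(unique(flat_y)) == 2L) roc_auc(flat_s, flat_y) else NA_real_
  micro_ap <- if (sum(flat_y) >= 1L) average_precision(flat_s, flat_y) else NA_real_
  top1 <- top_k_accuracy(scores, yv, 1L, warn = FALSE)
  top3 <- if (C >= 3L) top_k_accuracy(scores, yv, 3L, warn = FALSE) else NA_real_
  structure(
    list(
      class_names = class_names,
      per_class_auc = stats::setNames(auc, class_names),
      per_class_ap = stats::setNames(ap, class_names),
      macro_auc = mean(auc, na.rm = TRUE),
      macro_ap = mean(ap, na.rm = TRUE),
      micro_auc = micro_auc, micro_ap = micro_ap,
      top1_accuracy = top1, top3_accuracy = top3,
      undefined_classes = undefined,
      roc_points = roc_list, pr_points = pr_list,
      n_samples = nrow(yv)
    ),
    class = "cac_eval_report"
  )
}

#' @export
print.cac_eval_report <- function(x, ...) {
  cat(sprintf("<evaluation over %d samples, %d classes>\n", x$n_samples,
              length(x$class_names)))
  cat(sprintf("  macro AUC %.4f | macro AP %.4f | top-1 %.4f | top-3 %s\n",
              x$macro_auc, x$macro_ap, x$top1_accuracy,
              ifelse(is.na(x$top3_accuracy), "NA", sprintf("%.4f", x$top3_accuracy))))
  tab <- data.frame(class = x$class_names, auc = round(x$per_class_auc, 4),
                    ap = round(x$per_class_ap, 4), row.names = NULL)
  print(tab, row.names = FALSE)
  if (length(x$undefined_classes)) {
    cat("  metrics undefined (single-class labels) for:",
        paste(x$undefined_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read an evaluation report
#'
#' `write_report` emits a metrics table (`metrics.tsv`), per-class curve point
#' files (`roc_<class>.tsv`, `pr_<class>.tsv`) and a lossless serialized copy
#' (`report.rds`); `read_report` restores the serialized copy exactly.
#'
#' @param report a `cac_eval_report`.
#' @param dir output directory (created if missing).
#' @return `write_report` returns `dir` invisibly; `read_report` the report.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cac_eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- data.frame(
    class = c(report$class_names, "macro", "micro"),
    auc = c(report$per_class_auc, report$macro_auc, report$micro_auc),
    ap = c(report$per_class_ap, report$macro_ap, report$micro_ap)
  )
  utils::write.table(metrics, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- data.frame(metric = c("top1_accuracy", "top3_accuracy", "n_samples"),
                     value = c(report$top1_accuracy, report$top3_accuracy,
                               report$n_samples))
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cl in report$class_names) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cl)
    if (!is.null(report$roc_points[[cl]])) {
      utils::write.table(report$roc_points[[cl]], file.path(dir, paste0("roc_", safe, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(report$pr_points[[cl]])) {
      utils::write.table(report$pr_points[[cl]], file.path(dir, paste0("pr_", safe, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  saveRDS(report, file.path(dir, "report.rds"))
  invisible(dir)
}

#' @rdname write_report
#' @param path path to a directory written by `write_report` or directly to a
#'   `report.rds`.
#' @export
read_report <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "report.rds") else path
  if (!file.exists(f)) stopf("no serialized report at '%s'", path)
  x <- readRDS(f)
  if (!inherits(x, "cac_eval_report")) stopf("'%s' is not an evaluation report", f)
  x
}
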