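# AUC and ACC under the MedMNIST evaluation conventions, for all four task
# kinds, plus report emission.

# rank-based (Mann-Whitney) AUC of positive-class scores; ties count 0.5
binary_auc <- function(scores, y) {
  pos <- y == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve, MedMNIST conventions
#'
#' Binary: rank-based AUC of the positive-class score with ties counted 0.5.
#' Multi-class and ordinal: unweighted (macro) mean of one-vs-rest AUCs over
#' the classes present in the labels. Multi-label: unweighted mean of
#' per-label AUCs over labels with both outcomes present. Classes or labels
#' skipped from a macro average are reported in the `"skipped"` attribute.
#'
#' @param scores `n x m` score matrix (any strictly monotone transform of the
#'   model's class scores gives the same AUC).
#' @param labels `n x 1` class indices (single-label) or `n x m` 0/1 matrix.
#' @param task a [kd_task()].
#' @return AUC in `[0, 1]`; an error if the binary case has only one outcome.
#' @export
#' @examples
#' auc_score(cbind(1 - c(.9, .8, .4, .2), c(.9, .8, .4, .2)),
#'           c(1, 0, 1, 0), kd_task("binary", 2))
auc_score <- function(scores, labels, task) {
  stopifnot(inherits(task, "kd_task"))
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) {
    kd_stop("scores must be finite", class = "kd_validation_error")
  }
  if (task$kind == "binary") {
    y <- as.vector(labels)
    a <- binary_auc(scores[, ncol(scores)], y)
    if (is.na(a)) {
      kd_stop("binary AUC undefined: labels contain only one outcome",
              class = "kd_metric_error")
    }
    return(a)
  }
  if (task$kind == "multilabel") {
    ymat <- as.matrix(labels)
    per <- vapply(seq_len(ncol(ymat)), function(l) {
      binary_auc(scores[, l], ymat[, l])
    }, numeric(1))
  } else {
    y <- as.vector(labels)
    per <- vapply(seq_len(task$m) - 1L, function(k) {
      binary_auc(scores[, k + 1L], as.integer(y == k))
    }, numeric(1))
  }
  keep <- !is.na(per)
  if (!any(keep)) {
    kd_stop("AUC undefined: no class/label has both outcomes present",
            class = "kd_metric_error")
  }
  out <- mean(per[keep])
  attr(out, "skipped") <- which(!keep) - if (task$kind == "multilabel") 0L else 1L
  out
}

#' Classification accuracy, MedMNIST conventions
#'
#' Single-label (multiclass, ordinal): argmax prediction, ties resolved to the
#' lowest class index. Binary: positive-class probability thresholded at 0.5.
#' Multi-label: per-label 0.5 threshold, accuracy averaged unweighted over
#' labels.
#'
#' @param scores `n x m` probability (or score) matrix; thresholded branches
#'   assume probabilities.
#' @param labels as in [auc_score()].
#' @param task a [kd_task()].
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_score <- function(scores, labels, task) {
  stopifnot(inherits(task, "kd_task"))
  scores <- as.matrix(scores)
  if (task$kind == "binary") {
    y <- as.vector(labels)
    pred <- as.integer(scores[, ncol(scores)] >= 0.5)
    return(mean(pred == y))
  }
  if (task$kind == "multilabel") {
    ymat <- as.matrix(labels)
    pred <- (scores >= 0.5) * 1L
    return(mean(colMeans(pred == ymat)))
  }
  y <- as.vector(labels)
  pred <- max.col(scores, ties.method = "first") - 1L
  mean(pred == y)
}

#' Evaluate a model on one split of a dataset
#'
#' Probabilities are formed at temperature 1 — softmax for cross-entropy
#' tasks, per-label sigmoid for binary/multi-label — then scored with
#' [auc_score()] and [accuracy_score()]. Deterministic given model and data.
#'
#' @param model a materialized `kd_model` with a head.
#' @param bundle a `kd_bundle`.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @param target_side,normalization preprocessing, as in [preprocess_batch()].
#' @param model_tag label recorded in the report.
#' @return a `kd_metrics` report: `model`, `task`, `split`, `n`, `auc`, `acc`.
#' @export
evaluate_model <- function(model, bundle, split = "test", target_side = 28,
                           normalization = "none", model_tag = NULL) {
  stopifnot(inherits(bundle, "kd_bundle"), split %in% c("train", "val", "test"))
  if (model$task$kind != bundle$task$kind || model$task$m != bundle$task$m) {
    kd_stop("model task does not match bundle task",
            class = "kd_validation_error")
  }
  images <- bundle[[split]]$images
  if (dim(images)[1] == 0L) {
    kd_stop(sprintf("split '%s' is empty", split), class = "kd_validation_error")
  }
  probs <- predict(model, images, type = "prob", target_side = target_side,
                   normalization = normalization)
  report_metrics(probs, bundle[[split]]$labels, bundle$task, split,
                 model_tag %||% paste(model$arch, model$role))
}

report_metrics <- function(probs, labels, task, split, model_tag) {
  structure(
    list(model = model_tag, task = task$kind, split = split,
         n = nrow(as.matrix(probs)),
         auc = as.numeric(auc_score(probs, labels, task)),
         acc = accuracy_score(probs, labels, task)),
    class = "kd_metrics")
}

#' @export
print.kd_metrics <- function(x, ...) {
  cat(sprintf("<kd_metrics> %s | %s split (n=%d): AUC %.4f, ACC %.4f [%s]\n",
              x$model, x$split, x$n, x$auc, x$acc, x$task))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a `kd_metrics`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "kd_metrics"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
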