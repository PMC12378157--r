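# Task specification, NPZ loading, and batch preprocessing.

#' Construct a task specification
#'
#' A task is one of `binary`, `multiclass`, `multilabel`, `ordinal` with `m`
#' classes/labels. Single-label tasks (binary, multiclass, ordinal) use an
#' `n x 1` integer label layout with values in `0..m-1`; multi-label tasks use
#' an `n x m` 0/1 layout. The task kind selects the hard loss (binary
#' cross-entropy for binary and multi-label, cross-entropy otherwise) and the
#' AUC/ACC conventions.
#'
#' @param kind one of `"binary"`, `"multiclass"`, `"multilabel"`, `"ordinal"`.
#' @param m integer number of classes (labels for multi-label), `>= 2`.
#' @return a `kd_task` object.
#' @export
kd_task <- function(kind = c("binary", "multiclass", "multilabel", "ordinal"),
                    m) {
  kind <- match.arg(kind)
  check_scalar(m, "num_classes", integer = TRUE, lower = 2)
  if (kind == "binary" && m != 2) {
    kd_stop("field 'num_classes' must be 2 for a binary task",
            class = "kd_validation_error")
  }
  structure(
    list(kind = kind, m = as.integer(m),
         label_layout = if (kind == "multilabel") "n x m binary" else "n x 1 integer",
         single_label = kind != "multilabel",
         hard_loss = if (kind %in% c("binary", "multilabel")) "bce" else "ce"),
    class = "kd_task")
}

#' @export
print.kd_task <- function(x, ...) {
  cat(sprintf("<kd_task> %s, m = %d (%s labels, %s hard loss)\n",
              x$kind, x$m, x$label_layout, toupper(x$hard_loss)))
  invisible(x)
}

#' Infer the task specification from a label array
#'
#' Shape-based inference following the MedMNIST task taxonomy: `n x 1` integer
#' labels over `{0, 1}` are binary; `n x 1` with more than two distinct values
#' are multi-class; `n x L` (`L > 1`) 0/1 labels are multi-label with `m = L`.
#' Ordinal tasks cannot be told apart from multi-class by shape, so they are
#' never inferred — pass `override = "ordinal"`.
#'
#' @param labels integer vector or matrix of labels.
#' @param override optional `"ordinal"` declaration (single-label layout only).
#' @return a [kd_task()].
#' @export
infer_task_spec <- function(labels, override = NULL) {
  if (is.null(labels) || length(labels) == 0L) {
    kd_stop("labels are empty", class = "kd_validation_error")
  }
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    kd_stop("labels must be finite integers", class = "kd_validation_error")
  }
  L <- ncol(labels)
  if (L > 1L) {
    if (!all(labels %in% c(0L, 1L))) {
      kd_stop(sprintf(
        "n x %d label layout requires 0/1 values for multi-label inference", L),
        class = "kd_validation_error")
    }
    if (!is.null(override) && override != "multilabel") {
      kd_stop("task override is only supported for single-label layouts",
              class = "kd_validation_error")
    }
    return(kd_task("multilabel", L))
  }
  vals <- sort(unique(as.vector(labels)))
  if (any(vals < 0L)) {
    kd_stop("single-label values must be non-negative class indices",
            class = "kd_validation_error")
  }
  m <- as.integer(max(vals)) + 1L
  if (!is.null(override)) {
    if (!identical(override, "ordinal")) {
      kd_stop(sprintf("unknown task override '%s' (only 'ordinal' is accepted)",
                      override), class = "kd_validation_error")
    }
    return(kd_task("ordinal", max(m, 2L)))
  }
  if (all(vals %in% c(0L, 1L)) && m <= 2L) {
    return(kd_task("binary", 2L))
  }
  kd_task("multiclass", m)
}

#' Load a MedMNIST-style NPZ dataset
#'
#' Thin wrapper over [read_npz()] that attaches the inferred (or overridden)
#' task specification. No pixel values are modified.
#'
#' @inheritParams read_npz
#' @return a `kd_bundle`.
#' @export
load_medmnist_npz <- function(path, task_override = NULL) {
  read_npz(path, task_override = task_override)
}

# ---- preprocessing -----------------------------------------------------------

# Row-interpolation operator: S x H matrix R such that R %*% img resamples the
# H source rows to S target rows, bilinear, corners-not-aligned convention
# (target pixel centre i+0.5 maps to source coordinate (i+0.5)*H/S - 0.5).
bilinear_matrix <- function(S, H) {
  R <- matrix(0, S, H)
  src <- (seq_len(S) - 0.5) * H / S - 0.5
  src <- pmin(pmax(src, 0), H - 1)
  lo <- floor(src)
  w <- src - lo
  hi <- pmin(lo + 1, H - 1)
  for (i in seq_len(S)) {
    R[i, lo[i] + 1] <- R[i, lo[i] + 1] + (1 - w[i])
    R[i, hi[i] + 1] <- R[i, hi[i] + 1] + w[i]
  }
  R
}

#' Per-channel normalization statistics of an image array
#'
#' Computes per-channel mean and standard deviation of intensities scaled to
#' `[0, 1]`. Intended for the train split of a dataset, mirroring the common
#' practice of normalizing with training statistics. Channels with (near-)zero
#' spread get a standard deviation of 1, so constant images pass through
#' standardization unchanged.
#'
#' @param images integer image array, `n x H x W` or `n x H x W x 3`.
#' @param eps spread floor below which a channel is treated as constant.
#' @return list with numeric `mean` and `sd`, each of length 3.
#' @export
compute_norm_stats <- function(images, eps = 1e-8) {
  x <- images / 255
  if (length(dim(x)) == 3L) {
    m <- mean(x); s <- stats::sd(x)
    mean3 <- rep(m, 3); sd3 <- rep(s, 3)
  } else {
    mean3 <- apply(x, 4, mean)
    sd3 <- apply(x, 4, stats::sd)
  }
  sd3[!is.finite(sd3) | sd3 < eps] <- 1
  list(mean = mean3, sd = sd3)
}

#' Preprocess an image batch for model input
#'
#' Scales 8-bit intensities to `[0, 1]`, resizes bilinearly (corners not
#' aligned) to `target_side`, replicates grayscale to three identical
#' channels, then standardizes per channel. With `target_side` equal to the
#' source side and `normalization = "none"`, the map is channel replication
#' plus the `[0, 1]` intensity scaling only.
#'
#' @param images integer image array, `n x H x W` (grayscale) or
#'   `n x H x W x 3` (RGB), values in `[0, 255]`.
#' @param target_side target spatial side in pixels (the reference pipeline
#'   uses 224; desk-scale runs keep the native 28).
#' @param normalization `"none"`, or a list with per-channel `mean` and `sd`
#'   on the `[0, 1]` intensity scale (see [compute_norm_stats()]).
#' @return a `kd_batch`: list with `x`, a numeric array `n x 3 x S x S`, and
#'   provenance fields `source_side`, `target_side`, `normalization`.
#' @export
preprocess_batch <- function(images, target_side = 28, normalization = "none") {
  dm <- dim(images)
  if (!(length(dm) %in% c(3L, 4L))) {
    kd_stop("images must be n x H x W or n x H x W x 3",
            class = "kd_validation_error")
  }
  if (length(dm) == 4L && dm[4] != 3L) {
    kd_stop(sprintf("unsupported channel count %d (must be 1 or 3)", dm[4]),
            class = "kd_validation_error")
  }
  n <- dm[1]; H <- dm[2]; W <- dm[3]
  C <- if (length(dm) == 4L) 3L else 1L
  check_scalar(target_side, "target_side", integer = TRUE, lower = 1)
  S <- as.integer(target_side)
  x <- images / 255
  if (C == 1L) dim(x) <- c(n, H, W, 1L)
  # resize: operate on (H, W * n * C) then (W -> S) on the transposed layout
  if (S != H || S != W) {
    Ry <- bilinear_matrix(S, H)
    Rx <- bilinear_matrix(S, W)
    xp <- aperm(x, c(2, 3, 1, 4))            # H, W, n, C
    dim(xp) <- c(H, W * n * C)
    xp <- Ry %*% xp                          # S, W*n*C
    dim(xp) <- c(S, W, n, C)
    xp <- aperm(xp, c(2, 1, 3, 4))           # W, S, n, C
    dim(xp) <- c(W, S * n * C)
    xp <- Rx %*% xp                          # Sx, Sy*n*C
    dim(xp) <- c(S, S, n, C)                 # Sx, Sy, n, C
    x <- aperm(xp, c(3, 2, 1, 4))            # n, Sy (rows), Sx (cols), C
  }
  # replicate grayscale to 3 channels, reorder to n x 3 x S x S
  if (C == 1L) {
    x <- array(rep(as.vector(x), 3L), dim = c(n, S, S, 3L))
  }
  x <- aperm(x, c(1, 4, 2, 3)) # n, 3, S, S
  norm_tag <- "none"
  if (!identical(normalization, "none")) {
    if (!is.list(normalization) || is.null(normalization$mean) ||
        is.null(normalization$sd)) {
      kd_stop("normalization must be \"none\" or list(mean=, sd=)",
              class = "kd_validation_error")
    }
    mu <- rep_len(normalization$mean, 3L)
    sd <- rep_len(normalization$sd, 3L)
    sd[sd < 1e-8] <- 1
    for (c in 1:3) x[, c, , ] <- (x[, c, , ] - mu[c]) / sd[c]
    norm_tag <- sprintf("standardize(mean=%s, sd=%s)",
                        paste(signif(mu, 4), collapse = ","),
                        paste(signif(sd, 4), collapse = ","))
  }
  structure(list(x = x, source_side = c(H, W), target_side = S,
                 normalization = norm_tag),
            class = "kd_batch")
}
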