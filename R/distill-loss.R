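# The distillation loss mathematics: temperature softmax, t^2-scaled
# forward KL from teacher to student, hard-label losses, and the
# alpha/beta-weighted total.
#
# All losses are per-sample means over a batch, in nats (natural log).
# A floor of 1e-12 is applied inside logarithms.

LOG_FLOOR <- 1e-12

#' Distillation configuration
#'
#' Temperature `t > 0` and mixing weight `alpha` in `[0, 1]`. The distillation
#' weight `beta = 1 - alpha` is derived at construction and can never be set
#' independently. `alpha = 1` reduces training to plain hard-label supervision;
#' `alpha = 0` trains on the teacher's soft targets alone.
#'
#' @param temperature distillation temperature `t > 0`; larger values flatten
#'   the soft targets, exposing inter-class similarity structure.
#' @param alpha weight of the hard-label loss, in `[0, 1]`.
#' @return a `kd_distill_config` with fields `temperature`, `alpha`, `beta`.
#' @export
distill_config <- function(temperature = 2, alpha = 0.2) {
  check_scalar(temperature, "temperature")
  if (temperature <= 0) {
    kd_stop("field 'temperature' must be > 0", class = "kd_validation_error")
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  structure(list(temperature = temperature, alpha = alpha, beta = 1 - alpha),
            class = "kd_distill_config")
}

#' Temperature-scaled softmax
#'
#' `P_i = exp(z_i / t) / sum_j exp(z_j / t)`, computed with max-subtraction so
#' logit magnitudes up to at least 1e4 are safe. As `t` grows the distribution
#' tends to uniform.
#'
#' @param z numeric vector of `m` logits, or an `n x m` matrix (row-wise).
#' @param t temperature, `> 0`.
#' @return probability vector (or matrix) of the same shape; rows sum to 1.
#' @export
#' @examples
#' temperature_softmax(c(2, 0), t = 2)
temperature_softmax <- function(z, t) {
  check_scalar(t, "temperature")
  if (t <= 0) kd_stop("temperature must be > 0", class = "kd_validation_error")
  if (is.null(dim(z))) {
    zt <- z / t
    e <- exp(zt - max(zt))
    return(e / sum(e))
  }
  zt <- z / t
  e <- exp(zt - apply(zt, 1, max))
  e / rowSums(e)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `KL(p || q) = sum_i p_i ln(p_i / q_i)` in nats, with `0 ln 0 := 0`.
#' Requires `q > 0` wherever `p > 0`.
#'
#' @param p,q probability vectors of equal length (or `n x m` matrices,
#'   row-wise, returning a length-`n` vector).
#' @return non-negative divergence(s).
#' @export
#' @examples
#' kl_divergence(c(0.9, 0.1), c(0.5, 0.5))
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    kd_stop("p and q must have equal length", class = "kd_validation_error")
  }
  viol <- p > LOG_FLOOR & q <= 0
  if (any(viol)) {
    kd_stop("support violation: p > 0 where q = 0", class = "kd_numeric_error")
  }
  term <- p * (log(pmax(p, LOG_FLOOR)) - log(pmax(q, LOG_FLOOR)))
  term[p <= 0] <- 0
  if (is.null(dim(p))) sum(term) else rowSums(term)
}

#' Soft-target distillation loss
#'
#' The temperature-softened knowledge-transfer term: both logit vectors are
#' converted to temperature-`t` distributions and the forward KL divergence
#' from the (fixed) teacher distribution to the student distribution is
#' scaled by `t^2`, which keeps the soft-loss gradient magnitude comparable
#' across temperatures so the alpha/beta balance is temperature-invariant.
#' Batch inputs (`n x m` matrices) return the per-sample mean.
#'
#' @param teacher_z,student_z logit vector(s) of equal shape.
#' @param t temperature `> 0`.
#' @return scalar loss in nats, `>= 0`; zero iff the two temperature-`t`
#'   distributions coincide.
#' @export
soft_target_kl_loss <- function(teacher_z, student_z, t) {
  if (length(teacher_z) != length(student_z)) {
    kd_stop("teacher and student logits must have equal shape",
            class = "kd_validation_error")
  }
  pT <- temperature_softmax(teacher_z, t)
  pS <- temperature_softmax(student_z, t)
  t^2 * mean(kl_divergence(pT, pS))
}

#' Multi-label soft-target loss
#'
#' The softmax-based distillation term is undefined for multi-label targets,
#' where each label carries an independent probability. This extension treats
#' each label's temperature-scaled sigmoid as a two-point distribution and
#' averages the `t^2`-scaled binary KL divergences over labels (and over the
#' batch for matrix inputs).
#'
#' @inheritParams soft_target_kl_loss
#' @return scalar loss in nats, `>= 0`.
#' @export
multilabel_soft_loss <- function(teacher_z, student_z, t) {
  check_scalar(t, "temperature")
  if (t <= 0) kd_stop("temperature must be > 0", class = "kd_validation_error")
  if (length(teacher_z) != length(student_z)) {
    kd_stop("teacher and student logits must have equal shape",
            class = "kd_validation_error")
  }
  pT <- sigmoid(teacher_z / t)
  pS <- sigmoid(student_z / t)
  pT <- pmin(pmax(pT, LOG_FLOOR), 1 - LOG_FLOOR)
  pS <- pmin(pmax(pS, LOG_FLOOR), 1 - LOG_FLOOR)
  kl <- pT * (log(pT) - log(pS)) + (1 - pT) * (log1p(-pT) - log1p(-pS))
  t^2 * mean(kl)
}

#' Hard-label loss
#'
#' Single-label tasks (multiclass, ordinal) use cross-entropy on the
#' temperature-1 softmax: `-ln P_hard[y]`. Binary and multi-label tasks use
#' the mean per-label binary cross-entropy on per-label sigmoid probabilities
#' (binary labels are expanded to a 2-column one-hot layout). Batch inputs
#' return the per-sample mean.
#'
#' @param student_z logit vector (length `m`) or `n x m` matrix.
#' @param label class index in `0..m-1` (single-label; vector for batches) or
#'   0/1 label vector/matrix (multi-label).
#' @param task a [kd_task()].
#' @return scalar loss in nats, `>= 0`.
#' @export
hard_label_loss <- function(student_z, label, task) {
  stopifnot(inherits(task, "kd_task"))
  z <- if (is.null(dim(student_z))) matrix(student_z, nrow = 1) else student_z
  m <- ncol(z)
  if (m != task$m) {
    kd_stop(sprintf("logits have %d columns but task has m = %d", m, task$m),
            class = "kd_validation_error")
  }
  if (task$hard_loss == "ce") {
    y <- as.vector(label)
    if (length(y) != nrow(z)) {
      kd_stop("label count does not match logit rows",
              class = "kd_validation_error")
    }
    if (any(y < 0 | y >= m)) {
      kd_stop(sprintf("label out of range 0..%d", m - 1L),
              class = "kd_validation_error")
    }
    p <- temperature_softmax(z, 1)
    -mean(log(pmax(p[cbind(seq_len(nrow(z)), y + 1L)], LOG_FLOOR)))
  } else {
    ymat <- label_to_binary_matrix(label, nrow(z), m)
    p <- sigmoid(z)
    p <- pmin(pmax(p, LOG_FLOOR), 1 - LOG_FLOOR)
    -mean(ymat * log(p) + (1 - ymat) * log1p(-p))
  }
}

# binary task: expand n x 1 class indices to n x 2 one-hot; multilabel: pass
# through an n x m 0/1 matrix
label_to_binary_matrix <- function(label, n, m) {
  if (is.null(dim(label))) label <- matrix(label, ncol = if (length(label) == n) 1L else m)
  if (ncol(label) == m) {
    if (!all(label %in% c(0, 1))) {
      kd_stop("multi-label targets must be 0/1", class = "kd_validation_error")
    }
    return(label)
  }
  if (ncol(label) == 1L && m == 2L) {
    y <- as.vector(label)
    if (any(!y %in% c(0, 1))) {
      kd_stop("binary labels must be 0/1", class = "kd_validation_error")
    }
    return(cbind(1 - y, y))
  }
  kd_stop("label shape does not match the task", class = "kd_validation_error")
}

#' Combine hard and distillation losses
#'
#' `total = alpha * hard + (1 - alpha) * distill`. All three components are
#' retained; the total is a convex combination, so it always lies between the
#' two components.
#'
#' @param hard hard-label loss component (nats, `>= 0`).
#' @param distill distillation loss component (nats, `>= 0`).
#' @param cfg a [distill_config()] (or [train_config()]).
#' @return a `kd_loss` with fields `hard`, `distill`, `total`.
#' @export
total_loss <- function(hard, distill, cfg) {
  stopifnot(inherits(cfg, "kd_distill_config"))
  check_scalar(hard, "hard", lower = 0)
  check_scalar(distill, "distill", lower = 0)
  structure(list(hard = hard, distill = distill,
                 total = cfg$alpha * hard + cfg$beta * distill),
            class = "kd_loss")
}

#' @export
print.kd_loss <- function(x, ...) {
  cat(sprintf("<kd_loss> total %.6f = alpha*hard(%.6f) + beta*distill(%.6f)\n",
              x$total, x$hard, x$distill))
  invisible(x)
}
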