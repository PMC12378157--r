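# Phase-1 linear probing of the frozen teacher and phase-2 student
# distillation: Adam, multi-step learning-rate schedule, validation
# monitoring with early stopping, best-checkpoint selection.

#' Training configuration
#'
#' Extends [distill_config()] with the optimisation settings of the reference
#' pipeline: Adam from a base learning rate of 0.001, reduced by `gamma = 0.1`
#' at the start of epochs 50 and 75 (0-based indexing), up to 100 epochs with
#' early stopping on a validation metric.
#'
#' @inheritParams distill_config
#' @param base_lr initial learning rate.
#' @param milestones strictly increasing epoch indices (0-based, each
#'   `< epochs`) at which the learning rate is multiplied by `gamma`.
#' @param gamma multiplicative learning-rate decay, in `(0, 1]`.
#' @param epochs maximum number of epochs.
#' @param batch_size student minibatch size.
#' @param probe_batch_size linear-probe minibatch size.
#' @param patience early-stopping patience (epochs without improvement),
#'   `>= 1`.
#' @param monitor validation metric monitored for early stopping and best
#'   checkpoint: `"auc"`, `"acc"` (higher is better) or `"loss"` (validation
#'   total loss, lower is better).
#' @param seed master seed; all stochastic components derive named substreams
#'   from it (see [derive_seed()]).
#' @param cache_teacher_logits cache the frozen teacher's logits once instead
#'   of recomputing per epoch (identical trajectories either way, since the
#'   teacher is frozen; disable to save memory).
#' @return a `kd_train_config` (also a `kd_distill_config`).
#' @export
train_config <- function(temperature = 2, alpha = 0.2, base_lr = 0.001,
                         milestones = c(50, 75), gamma = 0.1, epochs = 100,
                         batch_size = 128, probe_batch_size = 32,
                         patience = 15, monitor = c("auc", "acc", "loss"),
                         seed = 0, cache_teacher_logits = TRUE) {
  base <- distill_config(temperature, alpha)
  monitor <- match.arg(monitor)
  check_scalar(base_lr, "base_lr", lower = 1e-12)
  check_scalar(gamma, "gamma", lower = 1e-12, upper = 1)
  check_scalar(epochs, "epochs", integer = TRUE, lower = 1)
  check_scalar(batch_size, "batch_size", integer = TRUE, lower = 1)
  check_scalar(probe_batch_size, "probe_batch_size", integer = TRUE, lower = 1)
  check_scalar(patience, "patience", integer = TRUE, lower = 1)
  check_scalar(seed, "seed", integer = TRUE)
  milestones <- as.integer(milestones)
  if (length(milestones)) {
    if (any(diff(milestones) <= 0) || any(milestones >= epochs) ||
        any(milestones < 0)) {
      kd_stop("field 'milestones' must be strictly increasing and < epochs",
              class = "kd_validation_error")
    }
  }
  structure(
    c(base,
      list(base_lr = base_lr, milestones = milestones, gamma = gamma,
           epochs = as.integer(epochs), batch_size = as.integer(batch_size),
           probe_batch_size = as.integer(probe_batch_size),
           patience = as.integer(patience), monitor = monitor,
           seed = as.integer(seed),
           cache_teacher_logits = isTRUE(cache_teacher_logits))),
    class = c("kd_train_config", "kd_distill_config"))
}

#' Learning rate at a given epoch
#'
#' Multi-step schedule: `base_lr * gamma^(number of milestones <= epoch)`,
#' milestones applied at the start of the named (0-based) epoch.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return the learning rate.
#' @export
#' @examples
#' cfg <- train_config()
#' lr_at_epoch(cfg, 10) # 0.001
#' lr_at_epoch(cfg, 60) # 0.0001
#' lr_at_epoch(cfg, 80) # 0.00001
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(inherits(cfg, "kd_train_config"))
  check_scalar(epoch, "epoch", integer = TRUE)
  if (epoch < 0 || epoch >= cfg$epochs) {
    kd_stop(sprintf("epoch %d out of range [0, %d)", epoch, cfg$epochs),
            class = "kd_validation_error")
  }
  # sequential multiplication so the decimal reference values (0.001, 0.0001,
  # 0.00001) are reproduced exactly in double precision
  lr <- cfg$base_lr
  for (i in seq_len(sum(cfg$milestones <= epoch))) lr <- lr * cfg$gamma
  lr
}

#' Early-stopping decision
#'
#' `TRUE` iff the monitored metric has not strictly improved for `patience`
#' consecutive epochs (ties count as no improvement; an improvement on the
#' last allowed epoch resets the counter).
#'
#' @param history a numeric vector of per-epoch monitored values, or a
#'   training-history `data.frame` holding a `val_<monitor>` column.
#' @param patience integer `>= 1`.
#' @param monitor `"auc"`, `"acc"`, or `"loss"` (used when `history` is a
#'   data.frame; also sets the improvement direction).
#' @return logical stop flag.
#' @export
early_stop_check <- function(history, patience, monitor = "auc") {
  if (is.data.frame(history)) {
    col <- paste0("val_", if (monitor == "loss") "total" else monitor)
    if (!col %in% names(history)) {
      kd_stop(sprintf("unknown monitored metric '%s'", monitor),
              class = "kd_validation_error")
    }
    history <- history[[col]]
  }
  if (!monitor %in% c("auc", "acc", "loss")) {
    kd_stop(sprintf("unknown monitored metric '%s'", monitor),
            class = "kd_validation_error")
  }
  if (length(history) == 0L) {
    kd_stop("history is empty", class = "kd_validation_error")
  }
  check_scalar(patience, "patience", integer = TRUE, lower = 1)
  v <- if (monitor == "loss") -as.numeric(history) else as.numeric(history)
  best <- v[1]
  since <- 0L
  for (i in seq_along(v)[-1]) {
    if (v[i] > best) {
      best <- v[i]
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(TRUE)
  }
  FALSE
}

# index of the best epoch: highest monitored value (lowest for loss),
# ties -> earliest
best_epoch_index <- function(values, monitor) {
  v <- if (monitor == "loss") -values else values
  which.max(v)
}

# ---- internal: gradients of the batch-mean losses w.r.t. student logits ------

hard_loss_grad <- function(z, label, task) {
  b <- nrow(z)
  if (task$hard_loss == "ce") {
    p <- temperature_softmax(z, 1)
    y <- as.vector(label)
    p[cbind(seq_len(b), y + 1L)] <- p[cbind(seq_len(b), y + 1L)] - 1
    p / b
  } else {
    ymat <- label_to_binary_matrix(label, b, ncol(z))
    (sigmoid(z) - ymat) / (b * ncol(z))
  }
}

distill_loss_grad <- function(z, zT, t, task) {
  b <- nrow(z)
  if (task$hard_loss == "ce") {
    t * (temperature_softmax(z, t) - temperature_softmax(zT, t)) / b
  } else {
    (t / ncol(z)) * (sigmoid(z / t) - sigmoid(zT / t)) / b
  }
}

batch_distill_loss <- function(zT, z, t, task) {
  if (task$hard_loss == "ce") soft_target_kl_loss(zT, z, t)
  else multilabel_soft_loss(zT, z, t)
}

# ---- linear probing -----------------------------------------------------------

#' Fit the teacher's linear head on frozen backbone features (phase 1)
#'
#' The backbone stays frozen — features are computed once and only the linear
#' head is trained, with the task's hard-label loss (no distillation term),
#' Adam, the multi-step schedule, early stopping, and best-validation head
#' selection.
#'
#' @param teacher a teacher `kd_model` (frozen backbone, trainable head),
#'   from [build_teacher()].
#' @param bundle a `kd_bundle`.
#' @param cfg a [train_config()].
#' @param target_side,normalization preprocessing applied before the backbone.
#' @return the teacher with its trained head; the training history is attached
#'   as attribute `"history"`.
#' @export
fit_linear_probe <- function(teacher, bundle, cfg, target_side = 28,
                             normalization = "none") {
  stopifnot(inherits(teacher, "kd_model"), inherits(bundle, "kd_bundle"),
            inherits(cfg, "kd_train_config"))
  require_params(teacher)
  task <- bundle$task
  if (teacher$task$kind != task$kind || teacher$task$m != task$m) {
    kd_stop("teacher task does not match bundle task",
            class = "kd_validation_error")
  }
  if (dim(bundle$train$images)[1] == 0L || dim(bundle$val$images)[1] == 0L) {
    kd_stop("empty split", class = "kd_validation_error")
  }
  ftr <- extract_features(teacher, bundle$train$images,
                          target_side = target_side,
                          normalization = normalization)
  fva <- extract_features(teacher, bundle$val$images,
                          target_side = target_side,
                          normalization = normalization)
  # probe in standardized feature space so the optimization is conditioned
  # independently of the backbone's feature scale; the affine transform is
  # folded back into the returned head below (same model class)
  f_mu <- colMeans(ftr)
  f_sd <- pmax(apply(ftr, 2, stats::sd), 1e-8)
  ftr <- sweep(sweep(ftr, 2, f_mu), 2, f_sd, "/")
  fva <- sweep(sweep(fva, 2, f_mu), 2, f_sd, "/")
  d <- ncol(ftr)
  m <- task$m
  head <- with_seed(derive_seed(cfg$seed, "probe.init"), list(
    head.weight = matrix(stats::rnorm(m * d, sd = sqrt(1 / d)), m, d),
    head.bias = numeric(m)
  ))
  opt <- adam_state(list(head.weight = c(m, d), head.bias = m))
  n <- nrow(ftr)
  ylab <- bundle$train$labels
  monitored <- numeric(0)
  best <- list(value = -Inf, head = head, epoch = 1L)
  hist_rows <- list()
  stop_reason <- "max_epochs"
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, epoch)
    idx <- with_seed(derive_seed(cfg$seed, paste0("probe.shuffle.", epoch)),
                     sample.int(n))
    chunks <- split(idx, ceiling(seq_along(idx) / cfg$probe_batch_size))
    tot <- 0
    for (ch in chunks) {
      f <- t(ftr[ch, , drop = FALSE])                 # d x b
      z <- t(head$head.weight %*% f + head$head.bias) # b x m
      yb <- ylab[ch, , drop = FALSE]
      tot <- tot + hard_label_loss(z, yb, task) * length(ch)
      dz <- t(hard_loss_grad(z, yb, task))            # m x b
      grads <- list(head.weight = tcrossprod(dz, f),  # m x d
                    head.bias = rowSums(dz))
      st <- adam_step(head, grads, opt, lr)
      head <- st$params
      opt <- st$state
    }
    zval <- t(head$head.weight %*% t(fva) + head$head.bias)
    probs <- scores_from_logits(zval, task)
    vauc <- as.numeric(auc_score(probs, bundle$val$labels, task))
    vacc <- accuracy_score(probs, bundle$val$labels, task)
    vloss <- hard_label_loss(zval, bundle$val$labels, task)
    hist_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, train_hard = tot / n, val_total = vloss,
      val_auc = vauc, val_acc = vacc)
    mon <- switch(cfg$monitor, auc = vauc, acc = vacc, loss = vloss)
    monitored <- c(monitored, mon)
    improved <- if (epoch == 0L) TRUE
      else if (cfg$monitor == "loss") mon < best$value else mon > best$value
    if (improved) best <- list(value = mon, head = head, epoch = epoch + 1L)
    if (early_stop_check(monitored, cfg$patience, cfg$monitor)) {
      stop_reason <- "early_stopping"
      break
    }
  }
  # fold the feature standardization into the head: W f_std + b =
  # (W / sd) f + (b - W mu / sd)
  W <- best$head$head.weight
  teacher$params$head.weight <- sweep(W, 2, f_sd, "/")
  teacher$params$head.bias <- as.vector(best$head$head.bias -
                                          W %*% (f_mu / f_sd))
  attr(teacher, "history") <- do.call(rbind, hist_rows)
  attr(teacher, "best_epoch") <- best$epoch - 1L
  attr(teacher, "stop_reason") <- stop_reason
  teacher
}

# ---- student training ----------------------------------------------------------

# Shared engine for supervised training and distillation. teacher = NULL
# means plain hard-label supervision (the alpha = 1 reduction).
train_student_engine <- function(student, bundle, cfg, teacher = NULL,
                                 target_side = 28, normalization = "none") {
  task <- bundle$task
  if (student$arch != "tiny") {
    kd_stop(paste0(
      "gradient-based training is implemented for the 'tiny' architecture; '",
      student$arch, "' provides construction, evaluation-mode inference and ",
      "parameter counting"), class = "kd_validation_error")
  }
  if (student$task$kind != task$kind || student$task$m != task$m) {
    kd_stop("student task does not match bundle task",
            class = "kd_validation_error")
  }
  for (s in c("train", "val")) {
    if (dim(bundle[[s]]$images)[1] == 0L) {
      kd_stop(sprintf("split '%s' is empty", s), class = "kd_validation_error")
    }
  }
  if (is.null(student$params)) student <- init_params(student, cfg$seed)
  btr <- preprocess_batch(bundle$train$images, target_side = target_side,
                          normalization = normalization)
  bva <- preprocess_batch(bundle$val$images, target_side = target_side,
                          normalization = normalization)
  n <- dim(btr$x)[1]
  distilling <- !is.null(teacher)
  zT_tr <- zT_va <- NULL
  teacher_logits <- function() {
    list(tr = predict(teacher, btr, type = "logit"),
         va = predict(teacher, bva, type = "logit"))
  }
  if (distilling && cfg$cache_teacher_logits) {
    tl <- teacher_logits()
    zT_tr <- tl$tr; zT_va <- tl$va
  }
  opt <- adam_state(student$shapes)
  monitored <- numeric(0)
  best <- list(value = NA_real_, params = student$params, epoch = 0L)
  hist_rows <- list()
  stop_reason <- "max_epochs"
  t <- cfg$temperature
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, epoch)
    if (distilling && !cfg$cache_teacher_logits) {
      tl <- teacher_logits()
      zT_tr <- tl$tr; zT_va <- tl$va
    }
    idx <- with_seed(derive_seed(cfg$seed, paste0("shuffle.", epoch)),
                     sample.int(n))
    chunks <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    sum_hard <- 0; sum_dist <- 0
    for (ch in chunks) {
      xb <- btr$x[ch, , , , drop = FALSE]
      yb <- bundle$train$labels[ch, , drop = FALSE]
      fw <- forward_tiny(student, xb, cache = TRUE)
      z <- fw$logits
      if (any(!is.finite(z))) {
        kd_stop(sprintf("non-finite logits at epoch %d", epoch),
                class = "kd_numeric_error")
      }
      hard <- hard_label_loss(z, yb, task)
      g <- cfg$alpha * hard_loss_grad(z, yb, task)
      dist <- 0
      if (distilling) {
        zTb <- zT_tr[ch, , drop = FALSE]
        dist <- batch_distill_loss(zTb, z, t, task)
        g <- g + cfg$beta * distill_loss_grad(z, zTb, t, task)
      }
      if (!is.finite(hard) || !is.finite(dist)) {
        kd_stop(sprintf("non-finite loss at epoch %d", epoch),
                class = "kd_numeric_error")
      }
      sum_hard <- sum_hard + hard * length(ch)
      sum_dist <- sum_dist + dist * length(ch)
      bw <- backward_tiny(student, fw, g)
      st <- adam_step(student$params, bw$grads, opt, lr)
      student$params <- st$params
      opt <- st$state
    }
    # validation
    zval <- forward_tiny(student, bva$x)$logits
    probs <- scores_from_logits(zval, task)
    vauc <- as.numeric(auc_score(probs, bundle$val$labels, task))
    vacc <- accuracy_score(probs, bundle$val$labels, task)
    vhard <- hard_label_loss(zval, bundle$val$labels, task)
    vdist <- if (distilling) batch_distill_loss(zT_va, zval, t, task) else 0
    vtotal <- cfg$alpha * vhard + cfg$beta * vdist
    tr_hard <- sum_hard / n
    tr_dist <- sum_dist / n
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      epoch = epoch, lr = lr,
      train_hard = tr_hard, train_distill = tr_dist,
      train_total = cfg$alpha * tr_hard + cfg$beta * tr_dist,
      val_hard = vhard, val_distill = vdist, val_total = vtotal,
      val_auc = vauc, val_acc = vacc)
    mon <- switch(cfg$monitor, auc = vauc, acc = vacc, loss = vtotal)
    monitored <- c(monitored, mon)
    improved <- if (is.na(best$value)) TRUE
      else if (cfg$monitor == "loss") mon < best$value else mon > best$value
    if (improved) {
      best <- list(value = mon, params = student$params, epoch = epoch)
    }
    if (early_stop_check(monitored, cfg$patience, cfg$monitor)) {
      stop_reason <- "early_stopping"
      break
    }
  }
  student$params <- best$params
  structure(
    list(student = student,
         history = do.call(rbind, hist_rows),
         config = cfg,
         task = task,
         teacher_tag = if (distilling) paste(teacher$arch, teacher$role) else NULL,
         mode = if (distilling) "distill" else "supervised",
         best_epoch = best$epoch,
         stop_reason = stop_reason,
         prep = list(target_side = target_side, normalization = normalization)),
    class = "kd_fit")
}

#' Distill a frozen teacher into a trainable student (phase 2)
#'
#' Each minibatch is passed through the frozen teacher (no gradient; logits
#' are cached across epochs by default, valid because the teacher never
#' changes) and the student; the student is updated by Adam on
#' `alpha * hard + (1 - alpha) * distill`, where the hard term is the task's
#' cross-entropy (or binary cross-entropy) against ground truth and the
#' distillation term is the `t^2`-scaled KL from the teacher's
#' temperature-softened distribution to the student's
#' ([soft_target_kl_loss()]; [multilabel_soft_loss()] for multi-label).
#' Validation AUC/ACC are computed each epoch; the best checkpoint by the
#' monitored metric is returned, with early stopping after `patience`
#' non-improving epochs.
#'
#' @param teacher a materialized, frozen-backbone teacher with a probed head
#'   (see [fit_linear_probe()]). Never modified.
#' @param student a student `kd_model` (architecture `"tiny"` at desk scale);
#'   initialised from `cfg$seed` if not yet materialized.
#' @param bundle a `kd_bundle`; teacher, student, and bundle tasks must agree.
#' @param cfg a [train_config()].
#' @param target_side,normalization preprocessing shared by both networks.
#' @return a `kd_fit`: the trained student, per-epoch history (losses,
#'   learning rate, validation AUC/ACC), best epoch, and stop reason.
#' @export
distill <- function(teacher, student, bundle, cfg, target_side = 28,
                    normalization = "none") {
  stopifnot(inherits(teacher, "kd_model"), inherits(student, "kd_model"),
            inherits(bundle, "kd_bundle"), inherits(cfg, "kd_train_config"))
  require_params(teacher)
  if (teacher$task$kind != bundle$task$kind ||
      teacher$task$m != bundle$task$m) {
    kd_stop("teacher task does not match bundle task",
            class = "kd_validation_error")
  }
  train_student_engine(student, bundle, cfg, teacher = teacher,
                       target_side = target_side,
                       normalization = normalization)
}

#' Train a student on hard labels only
#'
#' The plain supervised reference arm: no teacher, no distillation term —
#' operationally identical to [distill()] with `alpha = 1` (the two produce
#' the same parameter trajectory step for step at the same seed).
#'
#' @inheritParams distill
#' @return a `kd_fit`.
#' @export
train_supervised <- function(student, bundle, cfg, target_side = 28,
                             normalization = "none") {
  stopifnot(inherits(student, "kd_model"), inherits(bundle, "kd_bundle"),
            inherits(cfg, "kd_train_config"))
  train_student_engine(student, bundle, cfg, teacher = NULL,
                       target_side = target_side,
                       normalization = normalization)
}

# ---- kd_fit methods ------------------------------------------------------------

#' @export
print.kd_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("<kd_fit> %s student (%s), %d epochs (%s)\n",
              x$student$arch, x$mode, nrow(h), x$stop_reason))
  if (!is.null(x$teacher_tag)) {
    cat(sprintf("  teacher: %s | t = %g, alpha = %g\n",
                x$teacher_tag, x$config$temperature, x$config$alpha))
  }
  cat(sprintf("  best epoch %d by val %s; last val AUC %.4f, ACC %.4f\n",
              x$best_epoch, x$config$monitor, last$val_auc, last$val_acc))
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  h <- object$history
  best <- h[h$epoch == object$best_epoch, ]
  out <- list(mode = object$mode, epochs_run = nrow(h),
              stop_reason = object$stop_reason,
              best_epoch = object$best_epoch,
              best_val_auc = best$val_auc, best_val_acc = best$val_acc,
              final_lr = h$lr[nrow(h)],
              config = object$config)
  class(out) <- "summary.kd_fit"
  out
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  cat(sprintf("Distillation fit (%s): %d epochs, stopped by %s\n",
              x$mode, x$epochs_run, x$stop_reason))
  cat(sprintf("  temperature %g, alpha %g (beta %g)\n",
              x$config$temperature, x$config$alpha, x$config$beta))
  cat(sprintf("  best epoch %d: val AUC %.4f, val ACC %.4f\n",
              x$best_epoch, x$best_val_auc, x$best_val_acc))
  invisible(x)
}

#' @export
predict.kd_fit <- function(object, newdata, type = c("prob", "logit", "class"),
                           ...) {
  predict(object$student, newdata, type = match.arg(type),
          target_side = object$prep$target_side,
          normalization = object$prep$normalization, ...)
}

#' Plot training history
#'
#' Two base-graphics panels: loss components per epoch and validation
#' AUC/ACC per epoch, with the best epoch marked.
#'
#' @param x a `kd_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kd_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_total, type = "l", xlab = "epoch",
                 ylab = "loss (nats)", main = "training loss", ...)
  if (x$mode == "distill") {
    graphics::lines(h$epoch, h$train_hard, lty = 2)
    graphics::lines(h$epoch, h$train_distill, lty = 3)
    graphics::legend("topright", c("total", "hard", "distill"),
                     lty = 1:3, bty = "n", cex = 0.8)
  }
  graphics::plot(h$epoch, h$val_auc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "validation metric",
                 main = "validation", ...)
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("bottomright", c("AUC", "ACC"), lty = 1:2, bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Residual-style diagnostics: per-sample hard-loss contributions
#'
#' For single-label tasks, returns `-ln p[y]` per sample of the requested
#' split; for binary/multi-label, the per-sample mean binary cross-entropy.
#'
#' @param object a `kd_fit`.
#' @param bundle the data bundle to score.
#' @param split split name.
#' @param ... unused.
#' @export
residuals.kd_fit <- function(object, bundle, split = "train", ...) {
  z <- predict(object, bundle[[split]]$images, type = "logit")
  task <- object$task
  y <- bundle[[split]]$labels
  if (task$hard_loss == "ce") {
    p <- temperature_softmax(z, 1)
    -log(pmax(p[cbind(seq_len(nrow(z)), as.vector(y) + 1L)], LOG_FLOOR))
  } else {
    ymat <- label_to_binary_matrix(y, nrow(z), ncol(z))
    pr <- pmin(pmax(sigmoid(z), LOG_FLOOR), 1 - LOG_FLOOR)
    -rowMeans(ymat * log(pr) + (1 - ymat) * log1p(-pr))
  }
}
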