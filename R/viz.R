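# Penultimate-feature 2-D embeddings and class-evidence heatmaps.

# Binary-search conditional-Gaussian bandwidths so each row of the affinity
# matrix has the requested perplexity (standard t-SNE input kernel).
tsne_input_probs <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s < 1e-300) s <- 1e-300
      H <- log(s) + beta * sum(di * p) / s
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / s
  }
  P
}

#' Embed features in 2-D by t-distributed stochastic neighbor embedding
#'
#' Exact (non-Barnes-Hut) t-SNE: perplexity-calibrated Gaussian input
#' affinities, symmetrized; Student-t output kernel; gradient descent with
#' momentum (0.5 then 0.8 after iteration 250) and early exaggeration (x4 for
#' the first 100 iterations). Deterministic given the seed. Intended for
#' desk-scale `n` (a few hundred to a few thousand rows).
#'
#' @param features `n x d` feature matrix (e.g. from [extract_features()]).
#' @param seed mandatory integer seed for the random initialisation.
#' @param perplexity neighborhood-size parameter; requires `n > 3 * perplexity`.
#' @param labels optional per-row labels carried into the result.
#' @param iterations gradient-descent iterations.
#' @param learning_rate gradient step scale.
#' @return a `kd_embedding`: data.frame with `dim1`, `dim2`, and `label`.
#' @export
embed_features_2d <- function(features, seed, perplexity = 30,
                              labels = NULL, iterations = 400,
                              learning_rate = 100) {
  features <- as.matrix(features)
  n <- nrow(features)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(perplexity, "perplexity", lower = 2)
  if (n <= 3 * perplexity) {
    kd_stop(sprintf("too few rows (%d) for perplexity %g (need n > 3*perplexity)",
                    n, perplexity), class = "kd_validation_error")
  }
  sq <- rowSums(features^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(features)
  D2[D2 < 0] <- 0
  P <- tsne_input_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- with_seed(derive_seed(seed, "tsne.init"),
                 matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  for (iter in seq_len(iterations)) {
    exag <- if (iter <= 100) 4 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  out <- data.frame(dim1 = Y[, 1], dim2 = Y[, 2],
                    label = if (is.null(labels)) NA else as.vector(labels))
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perplexity
  attr(out, "model_tag") <- attr(features, "model_tag")
  class(out) <- c("kd_embedding", "data.frame")
  out
}

#' Write embedding coordinates to CSV
#'
#' @param embedding a `kd_embedding`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path) {
  utils::write.csv(as.data.frame(embedding), path, row.names = FALSE)
  invisible(path)
}

#' Class-evidence heatmap (gradient-weighted class activation map)
#'
#' Gradient-weighted class-activation mapping on the last convolutional
#' block. Both supported CNN architectures end in global average pooling
#' followed by a linear head, for which the gradient of a class logit with
#' respect to the last convolutional map is the head weight spread uniformly
#' over space — so the gradient-weighted map has the closed form
#' `relu(sum_k w[class, k] * A_k)`. The map is rectified, upsampled
#' bilinearly to the input size, and max-normalized to `[0, 1]`. If the class
#' logit carries no positive evidence anywhere (all-zero map), the map is
#' returned as zeros and flagged degenerate.
#'
#' @param model a materialized convolutional `kd_model` (`"tiny"` or
#'   `"resnet50"`) with a head.
#' @param image one image: `H x W` or `H x W x 3` integer array (or an
#'   `1 x H x W (x 3)` slice of a bundle).
#' @param target_class 0-based class index to explain.
#' @param target_side,normalization preprocessing, as in [preprocess_batch()].
#' @return a `kd_heatmap`: `side x side` matrix in `[0, 1]` with attributes
#'   `class` and `degenerate`.
#' @export
gradcam_heatmap <- function(model, image, target_class, target_side = 28,
                            normalization = "none") {
  stopifnot(inherits(model, "kd_model"))
  if (!model$arch %in% c("tiny", "resnet50")) {
    kd_stop(sprintf("heatmaps require a convolutional model, got '%s'",
                    model$arch), class = "kd_validation_error")
  }
  require_params(model)
  m <- model$task$m
  check_scalar(target_class, "target_class", integer = TRUE, lower = 0,
               upper = m - 1)
  dm <- dim(image)
  if (length(dm) == 2L) {
    dim(image) <- c(1L, dm)            # H x W grayscale
  } else if (length(dm) == 3L && dm[1] != 1L && dm[3] == 3L) {
    dim(image) <- c(1L, dm)            # H x W x 3 RGB
  } else if (!(dm[1] == 1L && length(dm) %in% c(3L, 4L))) {
    kd_stop("image must be a single H x W (x 3) array or a 1 x H x W (x 3) slice",
            class = "kd_validation_error")
  }
  batch <- preprocess_batch(image, target_side = target_side,
                            normalization = normalization)
  if (model$arch == "tiny") {
    fw <- forward_tiny(model, batch$x, cache = TRUE)
    cc <- fw$cache
    A <- array(cc$a3, dim = c(cc$c3, cc$S3, cc$S3)) # C x h x w
    side_small <- cc$S3
  } else {
    fw <- forward_resnet50(model, batch$x)
    A <- array(fw$act, dim = fw$act_dim)
    side_small <- fw$act_dim[2]
  }
  w <- model$params$head.weight[target_class + 1L, ] # d(logit)/d(GAP feature)
  Cn <- dim(A)[1]
  map <- matrix(0, side_small, side_small)
  for (k in seq_len(Cn)) map <- map + w[k] * A[k, , ]
  map[map < 0] <- 0
  degenerate <- max(map) <= 0
  S <- batch$target_side
  if (side_small != S) {
    R <- bilinear_matrix(S, side_small)
    map <- R %*% map %*% t(R)
    map[map < 0] <- 0
  }
  if (!degenerate) map <- map / max(map)
  structure(map, class = c("kd_heatmap", class(map)),
            class_index = target_class, degenerate = degenerate)
}

#' @export
print.kd_heatmap <- function(x, ...) {
  cat(sprintf("<kd_heatmap> %dx%d, class %d, range [%.3f, %.3f]%s\n",
              nrow(x), ncol(x), attr(x, "class_index"), min(x), max(x),
              if (attr(x, "degenerate")) " (degenerate: no positive evidence)"
              else ""))
  invisible(x)
}
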