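# Student and teacher network constructors, parameter counting, feature
# extraction, and checkpoints.
#
# A model is a list: arch tag, role, task, named parameter *shapes* (always
# present, enough to count parameters), named parameter arrays (materialized
# lazily — counting never allocates weights), non-trainable buffers (batch-norm
# running statistics), the names of frozen parameters, and the penultimate
# feature dimension. Convolution kernels are stored as (C*kh*kw) x Cout
# matrices in (channel, row, col) patch order; linear maps as (out x in).

VIT_DIMS <- list(
  s14 = list(D = 384L, depth = 12L, heads = 6L),
  b14 = list(D = 768L, depth = 12L, heads = 12L),
  l14 = list(D = 1024L, depth = 24L, heads = 16L)
)
VIT_PATCH <- 14L
VIT_POS_GRID <- 37L # native 518-pixel pretraining resolution / patch 14

new_kd_model <- function(arch, role, task, shapes, feature_dim,
                         params = NULL, buffers = NULL, frozen = character(),
                         meta = list()) {
  structure(
    list(arch = arch, role = role, task = task, shapes = shapes,
         params = params, buffers = buffers, frozen = frozen,
         feature_dim = feature_dim, meta = meta),
    class = "kd_model")
}

#' @export
print.kd_model <- function(x, ...) {
  cat(sprintf("<kd_model> %s (%s), task %s m=%s, features d=%d\n",
              x$arch, x$role,
              if (is.null(x$task)) "-" else x$task$kind,
              if (is.null(x$task)) "-" else x$task$m, x$feature_dim))
  cat(sprintf("  parameters: %s (%s)\n",
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$params)) "shapes only" else "materialized"))
  if (length(x$frozen)) {
    cat(sprintf("  frozen: %d of %d tensors\n",
                length(x$frozen), length(x$shapes)))
  }
  invisible(x)
}

# ---- shape builders ----------------------------------------------------------

tiny_cnn_shapes <- function(m, c1 = 8L, c2 = 16L, c3 = 32L) {
  list(
    conv1.weight = c(3L * 9L, c1), conv1.bias = c1,
    conv2.weight = c(c1 * 9L, c2), conv2.bias = c2,
    conv3.weight = c(c2 * 9L, c3), conv3.bias = c3,
    head.weight = c(m, c3), head.bias = m
  )
}

resnet50_shapes <- function(m) {
  shapes <- list(
    conv1.weight = c(3L * 49L, 64L),
    bn1.gamma = 64L, bn1.beta = 64L
  )
  blocks <- c(3L, 4L, 6L, 3L)
  planes <- c(64L, 128L, 256L, 512L)
  inplanes <- 64L
  for (st in 1:4) {
    p <- planes[st]
    for (bl in seq_len(blocks[st]) - 1L) {
      pre <- sprintf("layer%d.%d.", st, bl)
      cin <- if (bl == 0L) inplanes else 4L * p
      shapes[[paste0(pre, "conv1.weight")]] <- c(cin, p)
      shapes[[paste0(pre, "bn1.gamma")]] <- p
      shapes[[paste0(pre, "bn1.beta")]] <- p
      shapes[[paste0(pre, "conv2.weight")]] <- c(p * 9L, p)
      shapes[[paste0(pre, "bn2.gamma")]] <- p
      shapes[[paste0(pre, "bn2.beta")]] <- p
      shapes[[paste0(pre, "conv3.weight")]] <- c(p, 4L * p)
      shapes[[paste0(pre, "bn3.gamma")]] <- 4L * p
      shapes[[paste0(pre, "bn3.beta")]] <- 4L * p
      if (bl == 0L) {
        shapes[[paste0(pre, "downsample.conv.weight")]] <- c(cin, 4L * p)
        shapes[[paste0(pre, "downsample.bn.gamma")]] <- 4L * p
        shapes[[paste0(pre, "downsample.bn.beta")]] <- 4L * p
      }
    }
    inplanes <- 4L * p
  }
  shapes$head.weight <- c(m, 2048L)
  shapes$head.bias <- m
  shapes
}

resnet50_buffers <- function(shapes) {
  bn <- grep("\\.gamma$|^bn1\\.gamma$", names(shapes), value = TRUE)
  bn <- grep("gamma$", names(shapes), value = TRUE)
  buf <- list()
  for (g in bn) {
    base <- sub("gamma$", "", g)
    C <- shapes[[g]]
    buf[[paste0(base, "run_mean")]] <- numeric(C)
    buf[[paste0(base, "run_var")]] <- rep(1, C)
  }
  buf
}

vit_shapes <- function(variant, m = NULL) {
  d <- VIT_DIMS[[variant]]
  if (is.null(d)) {
    kd_stop(sprintf("unknown ViT variant '%s' (use s14, b14, l14)", variant),
            class = "kd_validation_error")
  }
  D <- d$D
  shapes <- list(
    cls_token = D,
    pos_embed = c(VIT_POS_GRID^2 + 1L, D),
    patch_embed.weight = c(3L * VIT_PATCH^2, D),
    patch_embed.bias = D
  )
  for (i in seq_len(d$depth) - 1L) {
    pre <- sprintf("blocks.%d.", i)
    shapes[[paste0(pre, "norm1.gamma")]] <- D
    shapes[[paste0(pre, "norm1.beta")]] <- D
    shapes[[paste0(pre, "attn.qkv.weight")]] <- c(D, 3L * D)
    shapes[[paste0(pre, "attn.qkv.bias")]] <- 3L * D
    shapes[[paste0(pre, "attn.proj.weight")]] <- c(D, D)
    shapes[[paste0(pre, "attn.proj.bias")]] <- D
    shapes[[paste0(pre, "ls1.gamma")]] <- D
    shapes[[paste0(pre, "norm2.gamma")]] <- D
    shapes[[paste0(pre, "norm2.beta")]] <- D
    shapes[[paste0(pre, "mlp.fc1.weight")]] <- c(D, 4L * D)
    shapes[[paste0(pre, "mlp.fc1.bias")]] <- 4L * D
    shapes[[paste0(pre, "mlp.fc2.weight")]] <- c(4L * D, D)
    shapes[[paste0(pre, "mlp.fc2.bias")]] <- D
    shapes[[paste0(pre, "ls2.gamma")]] <- D
  }
  shapes$norm.gamma <- D
  shapes$norm.beta <- D
  if (!is.null(m)) {
    shapes$head.weight <- c(m, D)
    shapes$head.bias <- m
  }
  shapes
}

# ---- construction ------------------------------------------------------------

#' Build a student model
#'
#' @param arch `"tiny"` (the desk-scale 3-conv-block CNN used throughout the
#'   test suite, ~24k parameters) or `"resnet50"` (the reference compact
#'   student; constructor, evaluation-mode forward pass and parameter-count
#'   contract — gradient-based training is provided for `"tiny"`).
#' @param task a [kd_task()]; the linear head maps features to `m` logits.
#' @param seed integer seed for deterministic weight initialisation; if
#'   `NULL`, only parameter shapes are constructed (enough for counting).
#' @return a `kd_model` with all parameters trainable.
#' @export
build_student <- function(arch = c("tiny", "resnet50"), task, seed = NULL) {
  arch <- match.arg(arch)
  stopifnot(inherits(task, "kd_task"))
  m <- task$m
  if (arch == "tiny") {
    model <- new_kd_model("tiny", "student", task, tiny_cnn_shapes(m),
                          feature_dim = 32L)
  } else {
    model <- new_kd_model("resnet50", "student", task, resnet50_shapes(m),
                          feature_dim = 2048L,
                          buffers = resnet50_buffers(resnet50_shapes(m)))
  }
  if (!is.null(seed)) model <- init_params(model, seed)
  model
}

#' Build a frozen-backbone teacher model
#'
#' The teacher couples a frozen feature backbone with a linear classification
#' head that is trainable only during probing ([fit_linear_probe()]). The
#' `"tiny"` backbone is the desk-scale CNN; `"s14"`, `"b14"`, `"l14"` are the
#' ViT variants of [build_vit_backbone()].
#'
#' @param backbone `"tiny"`, `"s14"`, `"b14"`, or `"l14"`.
#' @param task a [kd_task()].
#' @param seed seed for head (and, for `"tiny"`, backbone) initialisation;
#'   `NULL` constructs shapes only.
#' @param backbone_params optional named list of pretrained backbone parameter
#'   arrays (e.g. the backbone of a previously trained model).
#' @return a `kd_model` whose backbone tensors are marked frozen.
#' @export
build_teacher <- function(backbone = c("tiny", "s14", "b14", "l14"), task,
                          seed = NULL, backbone_params = NULL) {
  backbone <- match.arg(backbone)
  stopifnot(inherits(task, "kd_task"))
  m <- task$m
  if (backbone == "tiny") {
    shapes <- tiny_cnn_shapes(m)
    model <- new_kd_model("tiny", "teacher", task, shapes, feature_dim = 32L)
  } else {
    shapes <- vit_shapes(backbone, m = m)
    model <- new_kd_model(paste0("vit_", backbone), "teacher", task, shapes,
                          feature_dim = VIT_DIMS[[backbone]]$D)
  }
  model$frozen <- setdiff(names(model$shapes), c("head.weight", "head.bias"))
  if (!is.null(seed)) model <- init_params(model, seed)
  if (!is.null(backbone_params)) {
    for (nm in names(backbone_params)) {
      if (!nm %in% model$frozen) next
      want <- model$shapes[[nm]]
      got <- dim(backbone_params[[nm]]) %||% length(backbone_params[[nm]])
      if (!identical(as.integer(want), as.integer(got))) {
        kd_stop(sprintf("backbone tensor '%s': expected dim [%s], got [%s]",
                        nm, paste(want, collapse = ","),
                        paste(got, collapse = ",")),
                class = "kd_checkpoint_error")
      }
      model$params[[nm]] <- backbone_params[[nm]]
    }
  }
  model
}

#' Construct a ViT backbone with the published DINOv2 dimensions
#'
#' Patch size 14; embedding width/depth/heads 384/12/6 (`s14`), 768/12/12
#' (`b14`), 1024/24/16 (`l14`); MLP ratio 4; per-block layer-scale parameters;
#' class token; position embeddings sized for the 37x37 patch grid of the
#' native 518-pixel pretraining resolution, interpolated bilinearly at forward
#' time for other input sides (which must be multiples of 14).
#'
#' @param variant `"s14"`, `"b14"`, or `"l14"`.
#' @param pretrained_weights optional path to a checkpoint written by
#'   [save_checkpoint()]; each tensor is validated against the architecture
#'   and a mismatch is reported with the first offending tensor name.
#' @param seed seed for random initialisation; `NULL` keeps shapes only.
#' @return a backbone `kd_model` (no classification head; all tensors frozen).
#' @export
build_vit_backbone <- function(variant = c("s14", "b14", "l14"),
                               pretrained_weights = NULL, seed = NULL) {
  variant <- match.arg(variant)
  shapes <- vit_shapes(variant, m = NULL)
  model <- new_kd_model(paste0("vit_", variant), "backbone", NULL, shapes,
                        feature_dim = VIT_DIMS[[variant]]$D,
                        frozen = names(shapes))
  if (!is.null(seed)) model <- init_params(model, seed)
  if (!is.null(pretrained_weights)) {
    ck <- load_checkpoint(pretrained_weights)
    for (nm in names(shapes)) {
      p <- ck$params[[nm]]
      if (is.null(p)) {
        kd_stop(sprintf("weight file is missing tensor '%s'", nm),
                class = "kd_checkpoint_error")
      }
      got <- dim(p) %||% length(p)
      if (!identical(as.integer(shapes[[nm]]), as.integer(got))) {
        kd_stop(sprintf("tensor '%s': expected dim [%s], got [%s]",
                        nm, paste(shapes[[nm]], collapse = ","),
                        paste(got, collapse = ",")),
                class = "kd_checkpoint_error")
      }
    }
    model$params <- ck$params[names(shapes)]
  }
  model
}

#' Materialize model parameters with a deterministic initialisation
#'
#' He-normal for convolution kernels and ViT projections (scaled by fan-in),
#' unit batch-norm and layer-norm/layer-scale as published (layer-scale
#' 1e-5), zero biases. Same seed, same parameters, bit for bit.
#'
#' @param model a `kd_model`.
#' @param seed integer seed.
#' @return the model with `params` (and buffers where applicable) filled in.
#' @export
init_params <- function(model, seed) {
  check_scalar(seed, "seed", integer = TRUE)
  params <- with_seed(derive_seed(seed, paste0("init.", model$arch)), {
    out <- list()
    for (nm in names(model$shapes)) {
      d <- model$shapes[[nm]]
      n <- prod(d)
      v <- if (grepl("\\.gamma$", nm) && grepl("ls[12]", nm)) {
        rep(1e-5, n)                       # layer scale
      } else if (grepl("gamma$", nm)) {
        rep(1, n)                          # batch/layer norm scale
      } else if (grepl("beta$|bias$", nm) || nm == "cls_token") {
        numeric(n)
      } else if (nm == "pos_embed") {
        stats::rnorm(n, sd = 0.02)
      } else if (grepl("weight$", nm)) {
        fan_in <- if (length(d) == 2L) d[1] else d
        stats::rnorm(n, sd = sqrt(2 / fan_in))
      } else {
        stats::rnorm(n, sd = 0.02)
      }
      out[[nm]] <- if (length(d) > 1L) array(v, dim = d) else v
    }
    out
  })
  model$params <- params
  model
}

#' Count model parameters
#'
#' Counts elements over named parameter tensors (batch-norm running statistics
#' are buffers, not parameters, and are excluded — the convention under which
#' the reference architectures land on their published sizes).
#'
#' @param model a `kd_model`.
#' @param trainable_only if `TRUE`, frozen tensors are excluded.
#' @return exact integer-valued count (numeric to allow > 2^31).
#' @export
count_parameters <- function(model, trainable_only = FALSE) {
  stopifnot(inherits(model, "kd_model"))
  nms <- names(model$shapes)
  if (trainable_only) nms <- setdiff(nms, model$frozen)
  sum(vapply(model$shapes[nms], function(d) prod(as.numeric(d)), numeric(1)))
}

#' Parameter count floored to whole millions
#'
#' @param model a `kd_model`.
#' @inheritParams count_parameters
#' @return integer, `floor(count / 1e6)`.
#' @export
param_millions <- function(model, trainable_only = FALSE) {
  as.integer(floor(count_parameters(model, trainable_only) / 1e6))
}

# ---- forward passes ----------------------------------------------------------

require_params <- function(model) {
  if (is.null(model$params)) {
    kd_stop(sprintf(
      "model '%s' has no materialized parameters; call init_params()",
      model$arch), class = "kd_validation_error")
  }
}

# batch array (n,3,S,S) -> (3*S*S) x n column matrix, (C,H,W) order per sample
as_colmat <- function(x) {
  dm <- dim(x)
  matrix(aperm(x, c(2, 3, 4, 1)), dm[2] * dm[3] * dm[4], dm[1])
}

# Tiny CNN forward. x: kd_batch or (n,3,S,S) array. Returns logits (b x m),
# features (b x d), and, if cache = TRUE, everything backward needs.
forward_tiny <- function(model, x, cache = FALSE) {
  require_params(model)
  if (inherits(x, "kd_batch")) x <- x$x
  dm <- dim(x)
  S <- dm[3]
  if (S %% 4L != 0L) {
    kd_stop("tiny CNN needs an input side divisible by 4",
            class = "kd_validation_error")
  }
  p <- model$params
  xm <- as_colmat(x)
  b <- ncol(xm)
  c1 <- ncol(p$conv1.weight); c2 <- ncol(p$conv2.weight)
  c3 <- ncol(p$conv3.weight)
  f1 <- conv2d_forward(xm, 3L, S, S, p$conv1.weight, p$conv1.bias, 3L, 3L,
                       pad = 1L, keep_cols = cache)
  a1 <- relu(f1$out)
  p1 <- avgpool2_forward(a1, c1, S, S)
  S2 <- S %/% 2L
  f2 <- conv2d_forward(p1, c1, S2, S2, p$conv2.weight, p$conv2.bias, 3L, 3L,
                       pad = 1L, keep_cols = cache)
  a2 <- relu(f2$out)
  p2 <- avgpool2_forward(a2, c2, S2, S2)
  S3 <- S2 %/% 2L
  f3 <- conv2d_forward(p2, c2, S3, S3, p$conv3.weight, p$conv3.bias, 3L, 3L,
                       pad = 1L, keep_cols = cache)
  a3 <- relu(f3$out)
  feat <- gap_forward(a3, c3, S3, S3)             # d x b
  logits <- p$head.weight %*% feat + p$head.bias  # m x b
  out <- list(logits = t(logits), features = t(feat))
  if (cache) {
    out$cache <- list(xm = xm, S = S, S2 = S2, S3 = S3,
                      c1 = c1, c2 = c2, c3 = c3,
                      f1 = f1, a1 = a1, p1 = p1,
                      f2 = f2, a2 = a2, p2 = p2,
                      f3 = f3, a3 = a3, feat = feat)
  }
  out
}

# Exact gradients of the tiny CNN. dlogits: b x m upstream gradient.
# Returns grads for every parameter tensor plus d(conv3 post-ReLU activations).
backward_tiny <- function(model, fw, dlogits, need_dx = FALSE) {
  p <- model$params
  cc <- fw$cache
  dZ <- t(dlogits)                              # m x b
  grads <- list(
    head.weight = tcrossprod(dZ, cc$feat),      # m x d
    head.bias = rowSums(dZ)
  )
  dfeat <- crossprod(p$head.weight, dZ)         # d x b
  da3 <- gap_backward(dfeat, cc$c3, cc$S3, cc$S3)
  da3[cc$f3$out <= 0] <- 0
  b3 <- conv2d_backward(da3, cc$p2, cc$f3$cols, cc$f3$g, p$conv3.weight)
  grads$conv3.weight <- b3$dW; grads$conv3.bias <- b3$db
  dp2 <- b3$dx
  da2 <- avgpool2_backward(dp2, cc$c2, cc$S2, cc$S2)
  da2[cc$f2$out <= 0] <- 0
  b2 <- conv2d_backward(da2, cc$p1, cc$f2$cols, cc$f2$g, p$conv2.weight)
  grads$conv2.weight <- b2$dW; grads$conv2.bias <- b2$db
  dp1 <- b2$dx
  da1 <- avgpool2_backward(dp1, cc$c1, cc$S, cc$S)
  da1[cc$f1$out <= 0] <- 0
  b1 <- conv2d_backward(da1, cc$xm, cc$f1$cols, cc$f1$g, p$conv1.weight,
                        need_dx = need_dx)
  grads$conv1.weight <- b1$dW; grads$conv1.bias <- b1$db
  list(grads = grads, d_act3 = da3, dx = b1$dx)
}

# ResNet-50 forward, evaluation mode (batch-norm running statistics).
forward_resnet50 <- function(model, x) {
  require_params(model)
  if (inherits(x, "kd_batch")) x <- x$x
  p <- model$params
  buf <- model$buffers
  bn <- function(z, C, HW, base) {
    batchnorm_eval(z, C, HW, p[[paste0(base, "gamma")]],
                   p[[paste0(base, "beta")]],
                   buf[[paste0(base, "run_mean")]],
                   buf[[paste0(base, "run_var")]])
  }
  xm <- as_colmat(x)
  S <- dim(x)[3]
  f <- conv2d_forward(xm, 3L, S, S, p$conv1.weight, NULL, 7L, 7L,
                      stride = 2L, pad = 3L)
  H <- f$g$Ho
  z <- relu(bn(f$out, 64L, H * H, "bn1."))
  mp <- maxpool_forward(z, 64L, H, H, 3L, 2L, 1L)
  z <- mp$out; H <- mp$Ho
  C <- 64L
  blocks <- c(3L, 4L, 6L, 3L)
  planes <- c(64L, 128L, 256L, 512L)
  for (st in 1:4) {
    pl <- planes[st]
    for (blk in seq_len(blocks[st]) - 1L) {
      pre <- sprintf("layer%d.%d.", st, blk)
      stride <- if (blk == 0L && st > 1L) 2L else 1L
      f1 <- conv2d_forward(z, C, H, H, p[[paste0(pre, "conv1.weight")]], NULL,
                           1L, 1L)
      a <- relu(bn(f1$out, pl, H * H, paste0(pre, "bn1.")))
      f2 <- conv2d_forward(a, pl, H, H, p[[paste0(pre, "conv2.weight")]], NULL,
                           3L, 3L, stride = stride, pad = 1L)
      Hn <- f2$g$Ho
      a <- relu(bn(f2$out, pl, Hn * Hn, paste0(pre, "bn2.")))
      f3 <- conv2d_forward(a, pl, Hn, Hn, p[[paste0(pre, "conv3.weight")]],
                           NULL, 1L, 1L)
      a <- bn(f3$out, 4L * pl, Hn * Hn, paste0(pre, "bn3."))
      if (blk == 0L) {
        ds <- conv2d_forward(z, C, H, H,
                             p[[paste0(pre, "downsample.conv.weight")]], NULL,
                             1L, 1L, stride = stride)
        sc <- bn(ds$out, 4L * pl, Hn * Hn, paste0(pre, "downsample.bn."))
      } else {
        sc <- z
      }
      z <- relu(a + sc)
      H <- Hn
      C <- 4L * pl
    }
  }
  feat <- gap_forward(z, C, H, H)
  out <- list(features = t(feat), act = z, act_dim = c(C, H, H))
  if (!is.null(p$head.weight)) {
    out$logits <- t(p$head.weight %*% feat + p$head.bias)
  }
  out
}

layer_norm <- function(x, gamma, beta, eps = 1e-6) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc * xc)
  sweep(xc, 2, sqrt(v + eps), "/") * gamma + beta
}

gelu <- function(x) x * stats::pnorm(x)

# interpolate the 37x37 (+cls) position-embedding grid to a g x g grid
interpolate_pos_embed <- function(pos, g) {
  D <- ncol(pos)
  G <- VIT_POS_GRID
  if (g == G) return(pos)
  grid <- array(pos[-1, ], dim = c(G, G, D))
  R <- bilinear_matrix(g, G)
  a <- matrix(grid, G, G * D)
  a <- R %*% a                         # g x (G*D)
  a <- array(a, dim = c(g, G, D))
  a <- aperm(a, c(2, 1, 3))            # G x g x D
  a <- R %*% matrix(a, G, g * D)       # g x (g*D)
  a <- aperm(array(a, dim = c(g, g, D)), c(2, 1, 3))
  rbind(pos[1, , drop = FALSE], matrix(a, g * g, D))
}

# ViT forward, evaluation mode. Input side must be a multiple of 14.
forward_vit <- function(model, x) {
  require_params(model)
  if (inherits(x, "kd_batch")) x <- x$x
  p <- model$params
  dm <- dim(x)
  S <- dm[3]
  if (S %% VIT_PATCH != 0L) {
    kd_stop(sprintf("ViT input side must be a multiple of %d (got %d)",
                    VIT_PATCH, S), class = "kd_validation_error")
  }
  g <- S %/% VIT_PATCH
  b <- dm[1]
  D <- model$feature_dim
  depth <- sum(grepl("\\.norm1\\.gamma$", names(p)))
  heads <- VIT_DIMS[[sub("vit_", "", model$arch)]]$heads
  Dh <- D %/% heads
  xm <- as_colmat(x)
  geo <- conv_geometry(3L, S, S, VIT_PATCH, VIT_PATCH, VIT_PATCH, 0L)
  cols <- im2col(xm, geo)                       # (3*196) x (P*b)
  tok <- crossprod(p$patch_embed.weight, cols) + p$patch_embed.bias # D x (P*b)
  P <- g * g
  tok <- array(tok, dim = c(D, P, b))
  tokens <- array(0, dim = c(D, P + 1L, b))
  tokens[, 1L, ] <- p$cls_token
  tokens[, -1L, ] <- tok
  pos <- interpolate_pos_embed(p$pos_embed, g)  # (P+1) x D
  for (i in seq_len(b)) tokens[, , i] <- tokens[, , i] + t(pos)
  Tn <- P + 1L
  for (blk in seq_len(depth) - 1L) {
    pre <- sprintf("blocks.%d.", blk)
    xmat <- matrix(tokens, D, Tn * b)
    xn <- layer_norm(xmat, p[[paste0(pre, "norm1.gamma")]],
                     p[[paste0(pre, "norm1.beta")]])
    qkv <- crossprod(p[[paste0(pre, "attn.qkv.weight")]], xn) +
      p[[paste0(pre, "attn.qkv.bias")]]         # 3D x (Tn*b)
    qkv <- array(qkv, dim = c(D, 3L, Tn, b))
    attn_out <- array(0, dim = c(D, Tn, b))
    for (i in seq_len(b)) {
      for (h in seq_len(heads)) {
        rows <- ((h - 1L) * Dh + 1L):(h * Dh)
        q <- qkv[rows, 1L, , i]; k <- qkv[rows, 2L, , i]
        v <- qkv[rows, 3L, , i]                 # Dh x Tn
        A <- crossprod(q, k) / sqrt(Dh)         # Tn x Tn
        A <- exp(A - apply(A, 1, max))
        A <- A / rowSums(A)
        attn_out[rows, , i] <- v %*% t(A)
      }
    }
    ao <- crossprod(p[[paste0(pre, "attn.proj.weight")]],
                    matrix(attn_out, D, Tn * b)) +
      p[[paste0(pre, "attn.proj.bias")]]
    xmat <- xmat + p[[paste0(pre, "ls1.gamma")]] * ao
    xn <- layer_norm(xmat, p[[paste0(pre, "norm2.gamma")]],
                     p[[paste0(pre, "norm2.beta")]])
    h1 <- gelu(crossprod(p[[paste0(pre, "mlp.fc1.weight")]], xn) +
                 p[[paste0(pre, "mlp.fc1.bias")]])
    h2 <- crossprod(p[[paste0(pre, "mlp.fc2.weight")]], h1) +
      p[[paste0(pre, "mlp.fc2.bias")]]
    xmat <- xmat + p[[paste0(pre, "ls2.gamma")]] * h2
    tokens <- array(xmat, dim = c(D, Tn, b))
  }
  xmat <- layer_norm(matrix(tokens, D, Tn * b), p$norm.gamma, p$norm.beta)
  tokens <- array(xmat, dim = c(D, Tn, b))
  feat <- matrix(tokens[, 1L, ], D, b)          # class token
  out <- list(features = t(feat))
  if (!is.null(p$head.weight)) {
    out$logits <- t(p$head.weight %*% feat + p$head.bias)
  }
  out
}

# Architecture dispatch. Returns list(logits = b x m or NULL, features = b x d).
kd_forward <- function(model, x, cache = FALSE) {
  switch(model$arch,
    tiny = forward_tiny(model, x, cache = cache),
    resnet50 = forward_resnet50(model, x),
    vit_s14 = , vit_b14 = , vit_l14 = forward_vit(model, x),
    kd_stop(sprintf("unknown architecture '%s'", model$arch),
            class = "kd_validation_error"))
}

#' Extract penultimate-layer features
#'
#' Runs the model in evaluation mode (pure: two calls on the same batch agree
#' exactly) and returns the features immediately before the linear head.
#'
#' @param model a materialized `kd_model`.
#' @param images integer image array (`n x H x W` or `n x H x W x 3`) or a
#'   preprocessed `kd_batch`.
#' @param target_side,normalization forwarded to [preprocess_batch()] when
#'   `images` is a raw array.
#' @param batch_size evaluation minibatch size.
#' @return an `n x d` numeric matrix with attribute `model_tag`.
#' @export
extract_features <- function(model, images, target_side = 28,
                             normalization = "none", batch_size = 512L) {
  batch <- if (inherits(images, "kd_batch")) images else
    preprocess_batch(images, target_side = target_side,
                     normalization = normalization)
  x <- batch$x
  n <- dim(x)[1]
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  feats <- NULL
  for (ch in idx_chunks) {
    fw <- kd_forward(model, x[ch, , , , drop = FALSE])
    feats <- rbind(feats, fw$features)
  }
  if (any(!is.finite(feats))) {
    kd_stop("non-finite features extracted", class = "kd_numeric_error")
  }
  attr(feats, "model_tag") <- paste(model$arch, model$role)
  feats
}

#' Predict from a model
#'
#' @param object a materialized `kd_model` with a head.
#' @param newdata image array or `kd_batch`.
#' @param type `"prob"` (softmax for single-label tasks, per-label sigmoid
#'   for binary/multi-label), `"logit"`, or `"class"` (argmax / 0.5 threshold).
#' @param target_side,normalization,batch_size as in [extract_features()].
#' @param ... unused.
#' @return an `n x m` matrix (`"prob"`, `"logit"`) or an integer vector /
#'   0-1 matrix (`"class"`).
#' @export
predict.kd_model <- function(object, newdata, type = c("prob", "logit", "class"),
                             target_side = 28, normalization = "none",
                             batch_size = 512L, ...) {
  type <- match.arg(type)
  batch <- if (inherits(newdata, "kd_batch")) newdata else
    preprocess_batch(newdata, target_side = target_side,
                     normalization = normalization)
  x <- batch$x
  n <- dim(x)[1]
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  logits <- NULL
  for (ch in idx_chunks) {
    fw <- kd_forward(object, x[ch, , , , drop = FALSE])
    if (is.null(fw$logits)) {
      kd_stop("model has no classification head", class = "kd_validation_error")
    }
    logits <- rbind(logits, fw$logits)
  }
  if (type == "logit") return(logits)
  probs <- scores_from_logits(logits, object$task)
  if (type == "prob") return(probs)
  if (object$task$single_label) {
    max.col(probs, ties.method = "first") - 1L
  } else {
    (probs >= 0.5) * 1L
  }
}

# task-convention scores: softmax (t=1) for CE tasks, per-label sigmoid for
# BCE tasks (binary, multi-label)
scores_from_logits <- function(logits, task) {
  if (task$hard_loss == "ce") temperature_softmax(logits, 1) else sigmoid(logits)
}

# ---- checkpoints --------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file versioned schema: schema version, architecture tag, role, task,
#' parameter tensors, buffers, frozen-tensor names.
#'
#' @param model a `kd_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "kd_model"))
  saveRDS(list(schema = 1L, arch = model$arch, role = model$role,
               task = model$task, shapes = model$shapes,
               params = model$params, buffers = model$buffers,
               frozen = model$frozen, feature_dim = model$feature_dim),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return a `kd_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    kd_stop(sprintf("no such checkpoint: %s", path),
            class = "kd_checkpoint_error")
  }
  ck <- readRDS(path)
  if (!identical(ck$schema, 1L)) {
    kd_stop("unsupported checkpoint schema", class = "kd_checkpoint_error")
  }
  for (nm in names(ck$shapes)) {
    p <- ck$params[[nm]]
    if (is.null(p)) next
    got <- dim(p) %||% length(p)
    if (!identical(as.integer(ck$shapes[[nm]]), as.integer(got))) {
      kd_stop(sprintf("tensor '%s': expected dim [%s], got [%s]",
                      nm, paste(ck$shapes[[nm]], collapse = ","),
                      paste(got, collapse = ",")),
              class = "kd_checkpoint_error")
    }
  }
  new_kd_model(ck$arch, ck$role, ck$task, ck$shapes, ck$feature_dim,
               params = ck$params, buffers = ck$buffers, frozen = ck$frozen)
}
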