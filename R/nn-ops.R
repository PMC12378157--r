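# Minimal neural-network primitives on BLAS matrix products.
#
# Layout convention: a batch of feature maps is a matrix of dim (C*H*W) x b,
# column-major within a sample in (channel, row, column) order — channel
# fastest. Convolution is im2col + GEMM; its backward pass is the exact
# transpose (col2im scatter-add), so gradients are exact up to float
# round-off (verified against finite differences in the test suite).

# cache of im2col index maps keyed by geometry
.im2col_cache <- new.env(parent = emptyenv())

conv_geometry <- function(C, H, W, kh, kw, stride, pad) {
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  key <- paste(C, H, W, kh, kw, stride, pad, sep = "_")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  # linear index (1-based) of (c, y, x) in the padded volume, channel fastest
  lin <- function(c, y, x) c + C * (y - 1L) + C * Hp * (x - 1L)
  # rows of a patch: (C, kh, kw) order, matching a (C, kh, kw, Cout) kernel
  kc <- rep(seq_len(C), times = kh * kw)
  ky <- rep(rep(seq_len(kh), each = C), times = kw)
  kx <- rep(seq_len(kw), each = C * kh)
  # output positions: Ho fastest, then Wo
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  Ck <- C * kh * kw
  P <- Ho * Wo
  idx <- matrix(0L, Ck, P)
  for (p in seq_len(P)) {
    y0 <- (oy[p] - 1L) * stride
    x0 <- (ox[p] - 1L) * stride
    idx[, p] <- lin(kc, y0 + ky, x0 + kx)
  }
  # interior rows of the padded volume (where the unpadded input lives)
  ic <- rep(seq_len(C), times = H * W)
  iy <- rep(rep(seq_len(H) + pad, each = C), times = W)
  ix <- rep(seq_len(W) + pad, each = C * H)
  interior <- lin(ic, iy, ix)
  g <- list(C = C, H = H, W = W, kh = kh, kw = kw, stride = stride, pad = pad,
            Ho = Ho, Wo = Wo, Ck = Ck, P = P, Lp = C * Hp * Wp,
            idx = as.vector(idx), interior = interior)
  .im2col_cache[[key]] <- g
  g
}

# x: (C*H*W) x b. Returns the im2col matrix (Ck) x (P*b) plus geometry.
im2col <- function(x, g) {
  b <- ncol(x)
  if (g$pad > 0L) {
    xp <- matrix(0, g$Lp, b)
    xp[g$interior, ] <- x
  } else {
    xp <- x
  }
  cols <- xp[g$idx, , drop = FALSE] # (Ck*P) x b
  dim(cols) <- c(g$Ck, g$P * b)
  cols
}

# scatter-add transpose of im2col: dcols (Ck) x (P*b) -> dx (C*H*W) x b
col2im <- function(dcols, g, b) {
  dim(dcols) <- c(g$Ck * g$P, b)
  rs <- rowsum(dcols, group = g$idx) # sorted unique indices
  dxp <- matrix(0, g$Lp, b)
  dxp[as.integer(rownames(rs)), ] <- rs
  if (g$pad > 0L) dxp[g$interior, , drop = FALSE] else dxp
}

# Convolution forward. W_mat: (C*kh*kw) x Cout, bias: length Cout.
conv2d_forward <- function(x, C, H, W, W_mat, bias, kh, kw,
                           stride = 1L, pad = 0L, keep_cols = FALSE) {
  g <- conv_geometry(C, H, W, kh, kw, stride, pad)
  b <- ncol(x)
  cols <- im2col(x, g)
  out <- crossprod(W_mat, cols)        # (Cout) x (P*b)
  if (!is.null(bias)) out <- out + bias # recycles down columns (Cout fastest)
  Cout <- ncol(W_mat)
  dim(out) <- c(Cout * g$P, b)
  list(out = out, g = g, Cout = Cout,
       cols = if (keep_cols) cols else NULL)
}

# Convolution backward. dout: (Cout*P) x b. Returns dW, db and (unless
# need_dx = FALSE, e.g. at the first layer) dx.
conv2d_backward <- function(dout, x, cols, g, W_mat, need_dx = TRUE) {
  b <- ncol(dout)
  Cout <- ncol(W_mat)
  dim(dout) <- c(Cout, g$P * b)
  if (is.null(cols)) cols <- im2col(x, g)
  dW <- tcrossprod(cols, dout)      # (Ck) x (Cout)
  db <- rowSums(dout)
  dx <- NULL
  if (need_dx) {
    dcols <- W_mat %*% dout         # (Ck) x (P*b)
    dx <- col2im(dcols, g, b)
  }
  list(dW = dW, db = db, dx = dx)
}

# 2x2 average pooling (stride 2), H and W even, as row gathers: each pooled
# row averages four disjoint input rows, so forward and backward are index
# operations (backward is a permutation scatter).
.pool_cache <- new.env(parent = emptyenv())

avgpool2_index <- function(C, H, W) {
  key <- paste(C, H, W, sep = "_")
  if (!is.null(.pool_cache[[key]])) return(.pool_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  lin <- function(c, y, x) c + C * (y - 1L) + C * H * (x - 1L)
  cc <- rep(seq_len(C), times = Ho * Wo)
  yy <- rep(rep(seq_len(Ho), each = C), times = Wo)
  xx <- rep(seq_len(Wo), each = C * Ho)
  g <- list(
    i11 = lin(cc, 2L * yy - 1L, 2L * xx - 1L),
    i21 = lin(cc, 2L * yy, 2L * xx - 1L),
    i12 = lin(cc, 2L * yy - 1L, 2L * xx),
    i22 = lin(cc, 2L * yy, 2L * xx),
    n_in = C * H * W)
  .pool_cache[[key]] <- g
  g
}

avgpool2_forward <- function(x, C, H, W) {
  g <- avgpool2_index(C, H, W)
  (x[g$i11, , drop = FALSE] + x[g$i21, , drop = FALSE] +
   x[g$i12, , drop = FALSE] + x[g$i22, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dout, C, H, W) {
  g <- avgpool2_index(C, H, W)
  dx <- matrix(0, g$n_in, ncol(dout))
  d <- dout / 4
  dx[g$i11, ] <- d; dx[g$i21, ] <- d
  dx[g$i12, ] <- d; dx[g$i22, ] <- d
  dx
}

# max pooling via im2col over single channels (used by the ResNet stem, eval)
maxpool_forward <- function(x, C, H, W, k, stride, pad) {
  b <- ncol(x)
  g <- conv_geometry(1L, H, W, k, k, stride, pad)
  # split channels: view x as (C, H*W, b) -> per channel (H*W) x (C*b)
  xa <- array(x, dim = c(C, H * W, b))
  xc <- matrix(aperm(xa, c(2, 1, 3)), H * W, C * b)
  if (g$pad > 0L) {
    xp <- matrix(-Inf, g$Lp, C * b)
    xp[g$interior, ] <- xc
  } else xp <- xc
  cols <- xp[g$idx, , drop = FALSE]
  dim(cols) <- c(g$Ck, g$P * C * b)
  mx <- apply(cols, 2, max)
  out <- array(mx, dim = c(g$P, C, b))       # P x C x b
  out <- aperm(out, c(2, 1, 3))              # C x P x b
  dim(out) <- c(C * g$P, b)
  list(out = out, Ho = g$Ho, Wo = g$Wo)
}

# global average pooling: (C*H*W) x b -> C x b
gap_forward <- function(x, C, H, W) {
  rowsum(x, group = rep_len(seq_len(C), C * H * W)) / (H * W)
}

gap_backward <- function(dout, C, H, W) {
  dout[rep_len(seq_len(C), C * H * W), , drop = FALSE] / (H * W)
}

# batch norm, evaluation mode (running statistics): per-channel affine
batchnorm_eval <- function(x, C, HW, gamma, beta, run_mean, run_var, eps = 1e-5) {
  b <- ncol(x)
  scale <- gamma / sqrt(run_var + eps)
  shift <- beta - run_mean * scale
  a <- array(x, dim = c(C, HW, b))
  a <- a * scale + shift # recycles along C (fastest dim)
  dim(a) <- c(C * HW, b)
  a
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# ---- Adam --------------------------------------------------------------------

adam_state <- function(shapes) {
  zero <- function(d) if (length(d) > 1L) array(0, dim = d) else numeric(d)
  list(t = 0L, m = lapply(shapes, zero), v = lapply(shapes, zero))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
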