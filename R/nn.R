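# Minimal convolutional-network engine used by the dose predictor.
#
# Feature maps are stored as (B*H*W, C) matrices (batch of B images of
# H x W pixels, C channels; rows ordered image-major, column-major within
# an image). Convolutions run through cached im2col index plans so the
# heavy lifting is BLAS matrix multiplication. Layers are environments
# holding parameters, Adam state and forward caches; gradients flow
# through explicit backward functions. Small by design: the dose
# predictor needs seeded, CPU-only training on desk-scale problems, not a
# general autodiff system.

nn_cache <- new.env(parent = emptyenv())

# im2col plan: for a batch of B images H x W, kernel k, stride s, pad p.
# Returns list(idx = (npos x k^2) integer matrix of source rows, 0 = out
# of bounds; Ho, Wo, npos).
conv_plan <- function(B, H, W, k, s, p) {
  key <- paste(B, H, W, k, s, p, sep = "_")
  if (!is.null(nn_cache[[key]])) return(nn_cache[[key]])
  Ho <- (H + 2 * p - k) %/% s + 1
  Wo <- (W + 2 * p - k) %/% s + 1
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  idx1 <- matrix(0L, Ho * Wo, k * k)
  col <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    col <- col + 1L
    ri <- (oi - 1L) * s + di + 1L - p
    cj <- (oj - 1L) * s + dj + 1L - p
    ok <- ri >= 1L & ri <= H & cj >= 1L & cj <= W
    idx1[, col] <- ifelse(ok, ri + (cj - 1L) * H, 0L)
  }
  npos1 <- Ho * Wo
  if (B > 1L) {
    off <- rep((seq_len(B) - 1L) * H * W, each = npos1)
    idx <- idx1[rep(seq_len(npos1), times = B), , drop = FALSE]
    idx <- ifelse(idx > 0L, idx + off, 0L)
  } else idx <- idx1
  plan <- list(idx = idx, Ho = Ho, Wo = Wo, npos = npos1 * B)
  nn_cache[[key]] <- plan
  plan
}

im2col <- function(X, plan, C) {
  k2 <- ncol(plan$idx)
  cols <- matrix(0, plan$npos, k2 * C)
  for (o in seq_len(k2)) {
    id <- plan$idx[, o]
    ok <- id > 0L
    block <- matrix(0, plan$npos, C)
    block[ok, ] <- X[id[ok], , drop = FALSE]
    cols[, ((o - 1L) * C + 1L):(o * C)] <- block
  }
  cols
}

col2im <- function(dcols, plan, C, nrow_x) {
  dX <- matrix(0, nrow_x, C)
  k2 <- ncol(plan$idx)
  for (o in seq_len(k2)) {
    id <- plan$idx[, o]
    ok <- id > 0L
    if (!any(ok)) next
    dX[id[ok], ] <- dX[id[ok], , drop = FALSE] +
      dcols[ok, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  dX
}

new_conv <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$c_in <- c_in; e$c_out <- c_out; e$k <- k; e$s <- stride; e$p <- pad
  fan_in <- k * k * c_in
  e$W <- matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
  e$b <- numeric(c_out)
  e$gW <- 0 * e$W; e$gb <- 0 * e$b
  e
}

conv_forward <- function(e, X, B, H, W) {
  plan <- conv_plan(B, H, W, e$k, e$s, e$p)
  cols <- im2col(X, plan, e$c_in)
  Y <- cols %*% e$W
  Y <- sweep(Y, 2L, e$b, "+")
  e$cache <- list(cols = cols, plan = plan, nrow_x = nrow(X))
  list(Y = Y, H = plan$Ho, W = plan$Wo)
}

conv_backward <- function(e, dY) {
  e$gW <- e$gW + crossprod(e$cache$cols, dY)
  e$gb <- e$gb + colSums(dY)
  dcols <- dY %*% t(e$W)
  col2im(dcols, e$cache$plan, e$c_in, e$cache$nrow_x)
}

new_relu <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "relu"; e
}

relu_forward <- function(e, X) {
  e$mask <- X > 0
  X * e$mask
}

relu_backward <- function(e, dY) dY * e$mask

new_maxpool <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "maxpool"; e
}

maxpool_forward <- function(e, X, B, H, W, C) {
  plan <- conv_plan(B, H, W, 2L, 2L, 0L)
  cols <- im2col(X, plan, C)             # (npos, 4*C), offset-major blocks
  arr <- array(cols, c(plan$npos, C, 4L))
  Y <- arr[, , 1L, drop = TRUE]
  if (is.null(dim(Y))) Y <- matrix(Y, plan$npos, C)
  amax <- matrix(1L, plan$npos, C)
  for (o in 2:4) {
    v <- arr[, , o]
    upd <- v > Y
    Y[upd] <- v[upd]
    amax[upd] <- o
  }
  e$cache <- list(plan = plan, amax = amax, nrow_x = nrow(X), C = C)
  list(Y = Y, H = plan$Ho, W = plan$Wo)
}

maxpool_backward <- function(e, dY) {
  plan <- e$cache$plan; C <- e$cache$C
  dX <- matrix(0, e$cache$nrow_x, C)
  for (o in 1:4) {
    sel <- e$cache$amax == o          # (npos, C)
    if (!any(sel)) next
    id <- plan$idx[, o]
    pos_sel <- which(sel, arr.ind = TRUE)
    rows_x <- id[pos_sel[, 1L]]
    ok <- rows_x > 0L
    if (!any(ok)) next
    # each (input pixel, channel) receives from at most one pool window
    dX[cbind(rows_x[ok], pos_sel[ok, 2L])] <-
      dX[cbind(rows_x[ok], pos_sel[ok, 2L])] + dY[pos_sel[ok, , drop = FALSE]]
  }
  dX
}

# Fractionally-strided (transposed) convolution with kernel = stride = f:
# each input pixel expands into an f x f output block, restoring f-fold
# resolution exactly (no overlap, so the scatter is bijective).
new_deconv <- function(c_in, c_out, f = 8L) {
  e <- new.env(parent = emptyenv())
  e$type <- "deconv"
  e$c_in <- c_in; e$c_out <- c_out; e$f <- f
  fan_in <- c_in
  e$W <- matrix(stats::rnorm(c_in * f * f * c_out, 0, sqrt(2 / fan_in)),
                c_in, f * f * c_out)    # col = a + f*(b-1) + f^2*(o-1)
  e$b <- numeric(c_out)
  e$gW <- 0 * e$W; e$gb <- 0 * e$b
  e
}

deconv_plan <- function(B, h, w, f) {
  key <- paste("dc", B, h, w, f, sep = "_")
  if (!is.null(nn_cache[[key]])) return(nn_cache[[key]])
  H2 <- h * f; W2 <- w * f
  i2 <- rep(seq_len(H2), times = W2)
  j2 <- rep(seq_len(W2), each = H2)
  i <- (i2 - 1L) %/% f + 1L; a <- (i2 - 1L) %% f + 1L
  j <- (j2 - 1L) %/% f + 1L; b <- (j2 - 1L) %% f + 1L
  inrow1 <- i + (j - 1L) * h
  colsel <- a + f * (b - 1L)
  npix1 <- H2 * W2
  if (B > 1L) {
    off <- rep((seq_len(B) - 1L) * h * w, each = npix1)
    inrow <- rep(inrow1, times = B) + off
    colsel <- rep(colsel, times = B)
  } else inrow <- inrow1
  plan <- list(inrow = inrow, colsel = colsel, H2 = H2, W2 = W2,
               npix = npix1 * B)
  nn_cache[[key]] <- plan
  plan
}

deconv_forward <- function(e, X, B, h, w) {
  f <- e$f
  plan <- deconv_plan(B, h, w, f)
  Ybig <- X %*% e$W                    # (B*h*w, f^2 * c_out)
  Y <- matrix(0, plan$npix, e$c_out)
  for (o in seq_len(e$c_out)) {
    Y[, o] <- Ybig[cbind(plan$inrow, plan$colsel + f * f * (o - 1L))] + e$b[o]
  }
  e$cache <- list(X = X, plan = plan)
  list(Y = Y, H = plan$H2, W = plan$W2)
}

deconv_backward <- function(e, dY) {
  f <- e$f; plan <- e$cache$plan
  dYbig <- matrix(0, nrow(e$cache$X), f * f * e$c_out)
  for (o in seq_len(e$c_out)) {
    dYbig[cbind(plan$inrow, plan$colsel + f * f * (o - 1L))] <- dY[, o]
    e$gb[o] <- e$gb[o] + sum(dY[, o])
  }
  e$gW <- e$gW + crossprod(e$cache$X, dYbig)
  dYbig %*% t(e$W)
}

# Bottleneck residual block: 1x1 reduce -> 3x3 (optionally strided) ->
# 1x1 expand, plus identity or strided 1x1 projection shortcut.
new_bottleneck <- function(c_in, c_mid, c_out, stride = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "bottleneck"
  e$conv1 <- new_conv(c_in, c_mid, 1L, 1L, 0L)
  e$conv2 <- new_conv(c_mid, c_mid, 3L, stride, 1L)
  e$conv3 <- new_conv(c_mid, c_out, 1L, 1L, 0L)
  e$relu1 <- new_relu(); e$relu2 <- new_relu(); e$relu3 <- new_relu()
  e$proj <- if (c_in != c_out || stride != 1L) {
    new_conv(c_in, c_out, 1L, stride, 0L)
  } else NULL
  e$stride <- stride
  e
}

bottleneck_forward <- function(e, X, B, H, W) {
  f1 <- conv_forward(e$conv1, X, B, H, W)
  h1 <- relu_forward(e$relu1, f1$Y)
  f2 <- conv_forward(e$conv2, h1, B, f1$H, f1$W)
  h2 <- relu_forward(e$relu2, f2$Y)
  f3 <- conv_forward(e$conv3, h2, B, f2$H, f2$W)
  sc <- if (is.null(e$proj)) X else conv_forward(e$proj, X, B, H, W)$Y
  Y <- relu_forward(e$relu3, f3$Y + sc)
  list(Y = Y, H = f3$H, W = f3$W)
}

bottleneck_backward <- function(e, dY) {
  d <- relu_backward(e$relu3, dY)
  d3 <- conv_backward(e$conv3, d)
  d2 <- conv_backward(e$conv2, relu_backward(e$relu2, d3))
  dX <- conv_backward(e$conv1, relu_backward(e$relu1, d2))
  dX + if (is.null(e$proj)) d else conv_backward(e$proj, d)
}

# Collect parameterised sub-layers of a model (for the optimiser).
collect_params <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type %in% c("conv", "deconv")) out <- c(out, list(l))
    if (l$type == "bottleneck") {
      out <- c(out, list(l$conv1, l$conv2, l$conv3))
      if (!is.null(l$proj)) out <- c(out, list(l$proj))
    }
  }
  out
}

zero_grads <- function(params) {
  for (p in params) { p$gW <- 0 * p$gW; p$gb <- 0 * p$gb }
  invisible(NULL)
}

adam_init <- function(params) {
  for (p in params) {
    p$mW <- 0 * p$W; p$vW <- 0 * p$W
    p$mb <- 0 * p$b; p$vb <- 0 * p$b
  }
  invisible(NULL)
}

# Clip the global gradient norm (stabilises early training).
clip_grads <- function(params, max_norm = 1) {
  total <- sqrt(sum(vapply(params, function(p) sum(p$gW^2) + sum(p$gb^2),
                           numeric(1))))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    for (p in params) { p$gW <- p$gW * sc; p$gb <- p$gb * sc }
  }
  invisible(total)
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (p in params) {
    p$mW <- beta1 * p$mW + (1 - beta1) * p$gW
    p$vW <- beta2 * p$vW + (1 - beta2) * p$gW^2
    p$W <- p$W - lr * (p$mW / bc1) / (sqrt(p$vW / bc2) + eps)
    p$mb <- beta1 * p$mb + (1 - beta1) * p$gb
    p$vb <- beta2 * p$vb + (1 - beta2) * p$gb^2
    p$b <- p$b - lr * (p$mb / bc1) / (sqrt(p$vb / bc2) + eps)
  }
  invisible(NULL)
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), numeric(1)))
}
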