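# Minimal convolutional network machinery: im2col-based conv layers with
# manual backpropagation and an Adam optimizer. Arrays are (H, W, C),
# weights are (k*k*Cin) x Cout matrices so the forward pass is one GEMM.

conv_layer <- function(cin, cout, k = 3L, stride = 1L) {
  list(cin = cin, cout = cout, k = k, stride = stride,
       pad = (k - 1L) %/% 2L)
}

# He-normal initialization; RNG state is the caller's responsibility.
init_params <- function(layers) {
  lapply(layers, function(l) {
    fan_in <- l$k * l$k * l$cin
    list(W = matrix(rnorm(fan_in * l$cout, sd = sqrt(2 / fan_in)),
                    fan_in, l$cout),
         b = numeric(l$cout))
  })
}

conv_forward <- function(x, layer, par) {
  d <- dim(x)
  cols <- .cpp_im2col(x, d[1L], d[2L], d[3L], layer$k, layer$stride,
                      layer$pad)
  out <- cols %*% par$W
  out <- out + rep(par$b, each = nrow(out))
  Ho <- (d[1L] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  Wo <- (d[2L] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  dim(out) <- c(Ho, Wo, layer$cout)
  list(out = out, cols = cols, in_dim = d)
}

# need_dx = FALSE skips the input-gradient GEMM + col2im (first layer).
conv_backward <- function(dout, layer, par, cache, need_dx = TRUE) {
  d <- cache$in_dim
  dim(dout) <- c(length(dout) %/% layer$cout, layer$cout)
  dW <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dx <- if (need_dx)
    .cpp_col2im(tcrossprod(dout, par$W), d[1L], d[2L], d[3L],
                layer$k, layer$stride, layer$pad)
  else NULL
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_back <- function(dout, pre) { dout[pre <= 0] <- 0; dout }

sigmoid <- function(x) 1 / (1 + exp(-x))

# Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

downsum2 <- function(dout) {
  d <- dim(dout)
  h <- d[1L] %/% 2L; w <- d[2L] %/% 2L
  o <- dout[seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), , drop = FALSE] +
       dout[seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L), , drop = FALSE] +
       dout[seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L), , drop = FALSE] +
       dout[seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L), , drop = FALSE]
  o
}

# Feature-pyramid architecture: three encoder levels (strides 1, 2, 4),
# 1x1 lateral projections, nearest-neighbour top-down upsampling with
# additive merges, and two 1x1 heads (heatmap logits + EFD regression).
build_net <- function(n_harmonics, width = 8L) {
  w <- as.integer(width)
  nreg <- 2L + 4L * n_harmonics
  layers <- list(
    enc1  = conv_layer(1L, w, 3L, 1L),
    enc2  = conv_layer(w, 2L * w, 3L, 2L),
    enc3  = conv_layer(2L * w, 4L * w, 3L, 2L),
    enc3b = conv_layer(4L * w, 4L * w, 3L, 1L),
    lat3  = conv_layer(4L * w, 2L * w, 1L, 1L),
    lat2  = conv_layer(2L * w, 2L * w, 1L, 1L),
    lat1  = conv_layer(w, 2L * w, 1L, 1L),
    mrg2  = conv_layer(2L * w, 2L * w, 3L, 1L),
    mrg1  = conv_layer(2L * w, 2L * w, 3L, 1L),
    head_h = conv_layer(2L * w, 1L, 1L, 1L),
    head_r = conv_layer(2L * w, nreg, 1L, 1L))
  list(layers = layers, n_harmonics = n_harmonics, width = w, nreg = nreg,
       stride = 4L)
}

net_forward <- function(net, params, x, keep_cache = TRUE) {
  L <- net$layers
  cc <- list()
  f1 <- conv_forward(x, L$enc1, params$enc1);  a1 <- relu(f1$out)
  f2 <- conv_forward(a1, L$enc2, params$enc2); a2 <- relu(f2$out)
  f3 <- conv_forward(a2, L$enc3, params$enc3); a3 <- relu(f3$out)
  f3b <- conv_forward(a3, L$enc3b, params$enc3b); a3b <- relu(f3b$out)
  l3 <- conv_forward(a3b, L$lat3, params$lat3)
  l2 <- conv_forward(a2, L$lat2, params$lat2)
  l1 <- conv_forward(a1, L$lat1, params$lat1)
  p2pre <- upsample2(l3$out) + l2$out
  m2 <- conv_forward(p2pre, L$mrg2, params$mrg2); am2 <- relu(m2$out)
  p1pre <- upsample2(am2) + l1$out
  m1 <- conv_forward(p1pre, L$mrg1, params$mrg1); am1 <- relu(m1$out)
  hh <- conv_forward(am1, L$head_h, params$head_h)
  hr <- conv_forward(am1, L$head_r, params$head_r)
  if (keep_cache)
    cc <- list(f1 = f1, a1 = a1, f2 = f2, a2 = a2, f3 = f3, a3 = a3,
               f3b = f3b, a3b = a3b, l3 = l3, l2 = l2, l1 = l1,
               m2 = m2, am2 = am2, m1 = m1, am1 = am1, hh = hh, hr = hr)
  list(heat_logits = hh$out[, , 1L], reg = hr$out, cache = cc)
}

net_backward <- function(net, params, cache, dheat_logits, dreg) {
  L <- net$layers
  g <- list()
  dhl <- array(dheat_logits, c(dim(dheat_logits), 1L))
  bh <- conv_backward(dhl, L$head_h, params$head_h, cache$hh)
  br <- conv_backward(dreg, L$head_r, params$head_r, cache$hr)
  g$head_h <- bh; g$head_r <- br
  dam1 <- bh$dx + br$dx
  dm1 <- relu_back(dam1, cache$m1$out)
  bm1 <- conv_backward(dm1, L$mrg1, params$mrg1, cache$m1)
  g$mrg1 <- bm1
  dp1 <- bm1$dx
  bl1 <- conv_backward(dp1, L$lat1, params$lat1, cache$l1)
  g$lat1 <- bl1
  dam2 <- downsum2(dp1)
  dm2 <- relu_back(dam2, cache$m2$out)
  bm2 <- conv_backward(dm2, L$mrg2, params$mrg2, cache$m2)
  g$mrg2 <- bm2
  dp2 <- bm2$dx
  bl2 <- conv_backward(dp2, L$lat2, params$lat2, cache$l2)
  g$lat2 <- bl2
  dl3 <- downsum2(dp2)
  bl3 <- conv_backward(dl3, L$lat3, params$lat3, cache$l3)
  g$lat3 <- bl3
  da3b <- relu_back(bl3$dx, cache$f3b$out)
  b3b <- conv_backward(da3b, L$enc3b, params$enc3b, cache$f3b)
  g$enc3b <- b3b
  da3 <- relu_back(b3b$dx, cache$f3$out)
  b3 <- conv_backward(da3, L$enc3, params$enc3, cache$f3)
  g$enc3 <- b3
  da2 <- relu_back(b3$dx + bl2$dx, cache$f2$out)
  b2 <- conv_backward(da2, L$enc2, params$enc2, cache$f2)
  g$enc2 <- b2
  da1 <- relu_back(b2$dx + bl1$dx, cache$f1$out)
  b1 <- conv_backward(da1, L$enc1, params$enc1, cache$f1, need_dx = FALSE)
  g$enc1 <- b1
  lapply(g, function(e) list(W = e$dW, b = e$db))
}

adam_init <- function(params) {
  lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

# lr_mult: optional named per-layer learning-rate multipliers (heads
# supervised at a handful of pixels see noisy gradients, so Adam's
# effective travel there is far below lr * steps; a multiplier compensates
# at desk-scale step counts).
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, lr_mult = NULL) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    lrn <- lr * (if (!is.null(lr_mult) && !is.null(lr_mult[[nm]]))
                   lr_mult[[nm]] else 1)
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lrn * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lrn * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Penalty-reduced focal loss on the sigmoid heatmap (alpha = 2, beta = 4),
# normalized by the number of positive (peak) pixels.
heat_loss <- function(logits, target) {
  p <- sigmoid(logits)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  pos <- target >= 1 - 1e-9
  npos <- max(1, sum(pos))
  lpos <- -(1 - p)^2 * log(p)
  lneg <- -(1 - target)^4 * p^2 * log(1 - p)
  loss <- (sum(lpos[pos]) + sum(lneg[!pos])) / npos
  # d/dlogit via dL/dp * p(1-p)
  dpos <- 2 * p * (1 - p)^2 * log(p) - (1 - p)^3
  dneg <- -(1 - target)^4 * (2 * p^2 * (1 - p) * log(1 - p) - p^3)
  grad <- ifelse(pos, dpos, dneg) / npos
  dim(grad) <- dim(logits)
  list(loss = loss, grad = grad)
}

# Smooth-L1 on regression channels, evaluated at valid (center) pixels only:
# summed over channels, averaged over cells (normalizing by the channel
# count as well would dilute the regression gradient ~26x against the
# heatmap loss and stall shape learning). Sparse: computed at the few
# center pixels and scattered back into a zero array.
reg_loss <- function(reg, target, valid) {
  d <- dim(reg)
  nch <- d[3L]
  rows <- which(valid)
  grad <- array(0, d)
  if (length(rows) == 0L) return(list(loss = 0, grad = grad))
  hw <- d[1L] * d[2L]
  idx <- rep(rows, nch) + rep((seq_len(nch) - 1L) * hw, each = length(rows))
  e <- reg[idx] - target[idx]
  ae <- abs(e)
  small <- ae < 1
  denom <- length(rows)
  loss <- sum(ifelse(small, 0.5 * e^2, ae - 0.5)) / denom
  grad[idx] <- ifelse(small, e, sign(e)) / denom
  list(loss = loss, grad = grad)
}
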