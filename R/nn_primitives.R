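# Low-level differentiable layers.
#
# A feature map is a list(a, h, w, n): `a` is an S x C matrix with
# S = h*w*n and row index r = h0 + h*(w0 + w*n0) (0-based), i.e. image
# blocks are contiguous. Every *_fwd returns list(out, cache) and every
# *_bwd consumes (cache, dout) and returns the input gradient plus any
# parameter gradients. All arithmetic is double precision.

fmap <- function(a, h, w, n) list(a = a, h = h, w = w, n = n)

# Stack a list of [H, W, 3] arrays into a feature-map matrix.
images_to_fmap <- function(images) {
  H <- dim(images[[1]])[1]; W <- dim(images[[1]])[2]; C <- dim(images[[1]])[3]
  n <- length(images)
  x <- array(0, dim = c(H, W, n, C))
  for (i in seq_len(n)) x[, , i, ] <- images[[i]]
  dim(x) <- c(H * W * n, C)
  fmap(x, H, W, n)
}

conv_out_size <- function(size, k, stride, pad) (size + 2 * pad - k) %/% stride + 1

# ---- dense k x k convolution (stem), weight W: Cout x (Cin*k*k) ----
dense_conv_fwd <- function(fm, W, k, stride, pad) {
  cols <- cpp_im2col(fm$a, fm$h, fm$w, fm$n, k, stride, pad)
  ho <- conv_out_size(fm$h, k, stride, pad)
  wo <- conv_out_size(fm$w, k, stride, pad)
  list(out = fmap(cols %*% t(W), ho, wo, fm$n), cache = list(cols = cols))
}
dense_conv_bwd <- function(cache, dout) {
  list(dW = crossprod(dout, cache$cols))  # input gradient unused (stem layer)
}

# ---- 1 x 1 convolution over channels, weight W: Cout x Cin ----
pw_conv_fwd <- function(a, W) list(out = a %*% t(W), cache = list(a = a))
pw_conv_bwd <- function(cache, dout, W) {
  list(dx = dout %*% W, dW = crossprod(dout, cache$a))
}

# ---- depthwise convolution, weight Wk: (k*k) x C ----
dw_conv_fwd <- function(fm, Wk, k, stride, pad) {
  y <- cpp_dwconv(fm$a, fm$h, fm$w, fm$n, Wk, k, stride, pad)
  ho <- conv_out_size(fm$h, k, stride, pad)
  wo <- conv_out_size(fm$w, k, stride, pad)
  list(out = fmap(y, ho, wo, fm$n),
       cache = list(a = fm$a, h = fm$h, w = fm$w, n = fm$n,
                    k = k, stride = stride, pad = pad))
}
dw_conv_bwd <- function(cache, dout, Wk) {
  g <- cpp_dwconv_bwd(cache$a, dout, cache$h, cache$w, cache$n,
                      Wk, cache$k, cache$stride, cache$pad)
  list(dx = g$dx, dW = g$dw)
}

# ---- batch normalization over rows (spatial x batch), per channel ----
bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-3) {
  if (training) {
    st <- cpp_bn_stats(x)
    m <- st$mean; v <- st$var
    rmean <- (1 - momentum) * rmean + momentum * m
    rvar  <- (1 - momentum) * rvar + momentum * v
  } else {
    m <- rmean; v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  y <- cpp_bn_apply(x, m, inv, gamma, beta)
  # cache the layer input by reference; xhat is recomputed in the backward
  list(out = y, rmean = rmean, rvar = rvar,
       cache = list(x = x, m = m, inv = inv, gamma = gamma))
}
bn_bwd <- function(cache, dout) {
  r <- cpp_bn_bwd(dout, cache$x, cache$m, cache$inv, cache$gamma)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# Fused batch normalization + SiLU (the pervasive pair in the backbone):
# one pass and one allocation in each direction.
bn_silu_fwd <- function(x, gamma, beta, rmean, rvar, training,
                        momentum = 0.1, eps = 1e-3) {
  if (training) {
    st <- cpp_bn_stats(x)
    m <- st$mean; v <- st$var
    rmean <- (1 - momentum) * rmean + momentum * m
    rvar  <- (1 - momentum) * rvar + momentum * v
  } else {
    m <- rmean; v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  y <- cpp_bn_silu(x, m, inv, gamma, beta)
  list(out = y, rmean = rmean, rvar = rvar,
       cache = list(x = x, m = m, inv = inv, gamma = gamma, beta = beta))
}
bn_silu_bwd <- function(cache, dout) {
  r <- cpp_bn_silu_bwd(dout, cache$x, cache$m, cache$inv, cache$gamma, cache$beta)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# ---- activations ----
silu_fwd <- function(x) {
  list(out = cpp_silu(x), cache = list(x = x))
}
silu_bwd <- function(cache, dout) cpp_silu_bwd(cache$x, dout)

relu_fwd <- function(x) list(out = pmax(x, 0), cache = list(pos = x > 0))
relu_bwd <- function(cache, dout) dout * cache$pos

# ---- squeeze-and-excitation gate ----
# Global average pooling to an N x C descriptor, two fully connected layers
# (SiLU between, logistic after), then channel-wise rescaling of the map.
se_fwd <- function(fm, W1, b1, W2, b2) {
  HW <- fm$h * fm$w
  grp <- rep(seq_len(fm$n), each = HW)
  gap <- rowsum(fm$a, grp, reorder = FALSE) / HW            # N x C
  z1 <- addrow(gap %*% t(W1), b1)
  s1 <- plogis(z1); a1 <- z1 * s1                            # SiLU
  z2 <- addrow(a1 %*% t(W2), b2)
  g <- plogis(z2)                                            # gate in (0,1)
  y <- cpp_scale_by_gate(fm$a, g, HW)
  list(out = fmap(y, fm$h, fm$w, fm$n), gate = g,
       cache = list(a = fm$a, gap = gap, z1 = z1, s1 = s1, a1 = a1, g = g,
                    grp = grp, HW = HW))
}
se_bwd <- function(cache, dout, W1, W2) {
  da <- cpp_scale_by_gate(dout, cache$g, cache$HW)
  dg <- rowsum(dout * cache$a, cache$grp, reorder = FALSE)
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- crossprod(dz2, cache$a1); db2 <- colSums(dz2)
  da1 <- dz2 %*% W2
  dz1 <- da1 * (cache$s1 * (1 + cache$z1 * (1 - cache$s1)))
  dW1 <- crossprod(dz1, cache$gap); db1 <- colSums(dz1)
  dgap <- dz1 %*% W1
  da <- da + dgap[cache$grp, , drop = FALSE] / cache$HW
  list(dx = da, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- global average pooling to an N x C embedding ----
gap_fwd <- function(fm) {
  HW <- fm$h * fm$w
  grp <- rep(seq_len(fm$n), each = HW)
  list(out = rowsum(fm$a, grp, reorder = FALSE) / HW,
       cache = list(grp = grp, HW = HW))
}
gap_bwd <- function(cache, dout) dout[cache$grp, , drop = FALSE] / cache$HW

# ---- fully connected layer, weight W: out x in, bias b ----
fc_fwd <- function(x, W, b) list(out = addrow(x %*% t(W), b), cache = list(x = x))
fc_bwd <- function(cache, dout, W) {
  list(dx = dout %*% W, dW = crossprod(dout, cache$x), db = colSums(dout))
}

# ---- softmax / cross-entropy (log-sum-exp form) ----
softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy (nats) over a batch, plus the logit gradient.
cross_entropy_fwd <- function(logits, labels) {
  n <- nrow(logits)
  stopifnot(all(labels %in% 0:(ncol(logits) - 1)))
  zmax <- apply(logits, 1, max)
  lse <- zmax + log(rowSums(exp(logits - zmax)))
  picked <- logits[cbind(seq_len(n), labels + 1L)]
  loss <- mean(lse - picked)
  p <- softmax(logits)
  dlogits <- p
  dlogits[cbind(seq_len(n), labels + 1L)] <-
    dlogits[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# Mean absolute error over a batch, plus the prediction gradient.
mae_fwd <- function(pred, target) {
  n <- length(pred)
  list(loss = mean(abs(pred - target)), dpred = sign(pred - target) / n)
}
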