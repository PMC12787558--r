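# Brute-force oracles: plain-loop implementations used only as references.

# Dense/grouped k x k convolution by explicit enumeration; every scalar
# multiplication increments the counter. x: [H, W, Cin]; w: [k, k, Cin/g, Cout].
naive_conv <- function(x, w, stride, pad, groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  cpg_in <- Cin / groups; cpg_out <- Cout / groups
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, Cout))
  macs <- 0
  for (co in seq_len(Cout)) {
    g <- (co - 1) %/% cpg_out
    for (wo in seq_len(Wo)) {
      for (ho in seq_len(Ho)) {
        acc <- 0
        for (ci_loc in seq_len(cpg_in)) {
          ci <- g * cpg_in + ci_loc
          for (kw in seq_len(k)) {
            for (kh in seq_len(k)) {
              hi <- (ho - 1) * stride - pad + kh
              wi <- (wo - 1) * stride - pad + kw
              v <- if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) x[hi, wi, ci] else 0
              acc <- acc + v * w[kh, kw, ci_loc, co]
              macs <- macs + 1
            }
          }
        }
        out[ho, wo, co] <- acc
      }
    }
  }
  list(out = out, macs = macs)
}

# Fully connected layer by enumeration, counting in*out multiplications.
naive_fc <- function(x, W, b = NULL) {
  macs <- 0
  y <- numeric(nrow(W))
  for (o in seq_len(nrow(W))) {
    acc <- 0
    for (i in seq_len(ncol(W))) {
      acc <- acc + W[o, i] * x[i]
      macs <- macs + 1
    }
    y[o] <- acc + if (is.null(b)) 0 else b[o]
  }
  list(out = y, macs = macs)
}

# Walk a model configuration with instrumented naive layers on a random
# input, returning the total multiplication count actually performed.
naive_model_macs <- function(cfg) {
  bb <- cfg$backbone
  macs <- 0
  set.seed(1)
  x <- array(rnorm(bb$resolution^2 * 3), dim = c(bb$resolution, bb$resolution, 3))
  w <- array(rnorm(3 * 3 * 3 * bb$stem_ch), dim = c(3, 3, 3, bb$stem_ch))
  r <- naive_conv(x, w, 2, 1)
  macs <- macs + r$macs; x <- r$out
  for (b in treefusion:::backbone_blocks(bb)) {
    if (b$expand > 1) {
      w <- array(rnorm(b$cin * b$cmid), dim = c(1, 1, b$cin, b$cmid))
      r <- naive_conv(x, w, 1, 0)
      macs <- macs + r$macs; x <- r$out
    }
    w <- array(rnorm(b$k^2 * b$cmid), dim = c(b$k, b$k, 1, b$cmid))
    r <- naive_conv(x, w, b$stride, b$k %/% 2, groups = b$cmid)
    macs <- macs + r$macs; x <- r$out
    if (bb$use_se) {
      desc <- apply(x, 3, mean)
      r1 <- naive_fc(desc, matrix(rnorm(b$sq * b$cmid), b$sq))
      r2 <- naive_fc(r1$out, matrix(rnorm(b$cmid * b$sq), b$cmid))
      macs <- macs + r1$macs + r2$macs
    }
    w <- array(rnorm(b$cmid * b$cout), dim = c(1, 1, b$cmid, b$cout))
    r <- naive_conv(x, w, 1, 0)
    macs <- macs + r$macs; x <- r$out
  }
  w <- array(rnorm(dim(x)[3] * bb$head_ch), dim = c(1, 1, dim(x)[3], bb$head_ch))
  r <- naive_conv(x, w, 1, 0)
  macs <- macs + r$macs
  emb_img <- apply(r$out, 3, mean)
  # sensor MLP and heads
  s <- rnorm(cfg$sensor_dim)
  r1 <- naive_fc(s, matrix(rnorm(cfg$sensor_hidden * cfg$sensor_dim), cfg$sensor_hidden))
  r2 <- naive_fc(r1$out, matrix(rnorm(cfg$sensor_embed * cfg$sensor_hidden), cfg$sensor_embed))
  macs <- macs + r1$macs + r2$macs
  fus <- c(r2$out, emb_img)
  out_dim <- c(cls = cfg$n_classes, o2 = 1, co2 = 1)
  for (hd in cfg$heads) {
    h1 <- naive_fc(fus, matrix(rnorm(cfg$head_hidden * length(fus)), cfg$head_hidden))
    h2 <- naive_fc(h1$out, matrix(rnorm(out_dim[[hd]] * cfg$head_hidden), out_dim[[hd]]))
    macs <- macs + h1$macs + h2$macs
  }
  macs
}
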