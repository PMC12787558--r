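test_that("depthwise-separable stage follows the configured shape arithmetic", {
  # expansion 6 at 112x112x16-equivalent scaled down: 16px, 4 channels
  stages <- data.frame(expand = 6, kernel = 3, stride = 1, out_ch = 4, repeats = 1)
  bb <- custom_backbone_config(4, stages, 8, 16)
  cfg <- model_config(backbone = bb, sensor_dim = 3, use_sensor = FALSE,
                      head_hidden = 4, seed = 1)
  m <- build_model(cfg)
  fm <- treefusion:::images_to_fmap(random_images(2, 16))
  r <- treefusion:::forward_backbone(m, fm)
  # stem: 16 -> 8; stride-1 block keeps 8x8; head embedding width 8
  expect_equal(unname(r$cache$pre_pool[c("h", "w")]), c(8, 8))
  expect_equal(dim(r$emb), c(2, 8))
  # expansion channels: dw weight has cmid = 6 * cin columns
  expect_equal(ncol(m$params[["b01.dw.W"]]), 6 * 4)

  # stride-2 block halves odd/even sizes by ceiling division
  expect_equal(treefusion:::conv_out_size(112, 3, 2, 1), 56)
  expect_equal(treefusion:::conv_out_size(7, 5, 2, 2), 4)
})

test_that("cpp convolution kernels agree with a naive loop implementation", {
  set.seed(31)
  H <- 7; W <- 7; C <- 5; k <- 3
  x <- array(rnorm(H * W * C), dim = c(H, W, C))
  fm <- treefusion:::images_to_fmap(list(x))
  # depthwise, stride 2
  wk <- matrix(rnorm(k * k * C), k * k, C)
  got <- treefusion:::dw_conv_fwd(fm, wk, k, 2L, 1L)
  warr <- array(0, dim = c(k, k, 1, C))
  for (c in 1:C) warr[, , 1, c] <- matrix(wk[, c], k, k)  # kw*k + kh layout
  ref <- naive_conv(x, warr, 2, 1, groups = C)
  got_arr <- array(got$out$a, dim = c(got$out$h, got$out$w, C))
  expect_lt(max(abs(got_arr - ref$out)), 1e-10)
  # dense (stem-style), stride 2
  Cout <- 4
  Wd <- matrix(rnorm(Cout * C * k * k), Cout, C * k * k)
  gotd <- treefusion:::dense_conv_fwd(fm, Wd, k, 2L, 1L)
  warr2 <- array(0, dim = c(k, k, C, Cout))
  for (co in 1:Cout) for (ci in 1:C)
    warr2[, , ci, co] <- matrix(Wd[co, (ci - 1) * k * k + 1:(k * k)], k, k)
  refd <- naive_conv(x, warr2, 2, 1)
  gotd_arr <- array(gotd$out$a, dim = c(gotd$out$h, gotd$out$w, Cout))
  expect_lt(max(abs(gotd_arr - refd$out)), 1e-10)
})

test_that("squeeze-excitation matches a per-element loop oracle and contracts", {
  set.seed(7)
  h <- 4; w <- 4; C <- 8; n <- 2; sq <- 3
  imgs <- random_images(n, 4, seed = 7)
  imgs <- lapply(imgs, function(im) array(rnorm(h * w * C), dim = c(h, w, C)))
  # build the fmap by hand (C channels, not 3)
  arr <- array(0, dim = c(h, w, n, C))
  for (i in 1:n) arr[, , i, ] <- imgs[[i]]
  dim(arr) <- c(h * w * n, C)
  fm <- treefusion:::fmap(arr, h, w, n)
  W1 <- matrix(rnorm(sq * C), sq); b1 <- rnorm(sq)
  W2 <- matrix(rnorm(C * sq), C); b2 <- rnorm(C)
  r <- treefusion:::se_fwd(fm, W1, b1, W2, b2)
  silu <- function(x) x / (1 + exp(-x))
  for (i in 1:n) {
    desc <- apply(imgs[[i]], 3, mean)                     # GAP
    gate <- plogis(as.numeric(W2 %*% silu(as.numeric(W1 %*% desc + b1)) + b2))
    expect_true(all(gate > 0 & gate < 1))
    ref <- imgs[[i]]
    for (c in 1:C) ref[, , c] <- ref[, , c] * gate[c]
    got <- array(r$out$a[(i - 1) * h * w + 1:(h * w), ], dim = c(h, w, C))
    expect_lt(max(abs(got - ref)), 1e-6)
  }
  # elementwise contraction: |output| <= |input|
  expect_true(all(abs(r$out$a) <= abs(fm$a)))
  # channel constant at value c -> descriptor entry = c
  fm2 <- treefusion:::fmap(matrix(2.5, h * w, C), h, w, 1)
  r2 <- treefusion:::se_fwd(fm2, W1, b1, W2, b2)
  expect_equal(unname(r2$cache$gap[1, ]), rep(2.5, C))
  # zero gating weights force a 0.5 gate
  r3 <- treefusion:::se_fwd(fm, W1 * 0, b1 * 0, W2 * 0, b2 * 0)
  expect_equal(r3$out$a, fm$a * 0.5)
})

test_that("residual rule: applied iff stride 1 and matching channels; identity in the zero-projection limit", {
  blocks <- treefusion:::backbone_blocks(backbone_config("full"))
  resid <- vapply(blocks, `[[`, TRUE, "residual")
  strides <- vapply(blocks, `[[`, 1L, "stride")
  cins <- vapply(blocks, `[[`, 1L, "cin")
  couts <- vapply(blocks, `[[`, 1L, "cout")
  expect_identical(resid, strides == 1L & cins == couts)
  expect_false(any(resid[strides == 2L]))

  # zero projection weights + zero shift => block output equals its input
  m <- micro_model(seed = 5)
  m$params[["b03.proj.W"]][] <- 0    # residual-eligible repeat block (8 -> 8)
  fm <- treefusion:::images_to_fmap(random_images(1, 16, seed = 2))
  r <- treefusion:::forward_backbone(m, fm, training = FALSE)
  b <- treefusion:::backbone_blocks(m$cfg$backbone)[[3]]
  expect_true(b$residual)
  cache <- r$cache$blocks[[3]]
  # forward the block in isolation and compare
  fm_in <- treefusion:::fmap(cache$x_in, 4, 4, 1)
  rb <- treefusion:::mbconv_fwd(m$params, m$buffers, m$cfg$backbone, b, "b03",
                                fm_in, FALSE)
  expect_equal(rb$out$a, fm_in$a)
})

test_that("parameter counting: closed form equals instantiated model; stem is 928 at 32 channels", {
  m <- micro_model()
  expect_equal(count_params(m), count_params(m$cfg))
  # expansion factor 1 skips the expand convolution entirely
  expect_false("b01.exp.W" %in% names(m$params))
  expect_true("b02.exp.W" %in% names(m$params))
  tiny_cfg <- model_config(backbone = backbone_config("tiny"), sensor_dim = 30)
  expect_equal(count_params(build_model(tiny_cfg)), count_params(tiny_cfg))
  # 3x3 conv 3->32 bias-free plus batch-norm pair: 864 + 64
  stages <- data.frame(expand = 1, kernel = 3, stride = 1, out_ch = 32, repeats = 1)
  bb <- custom_backbone_config(32, stages, 8, 16)
  m32 <- build_model(model_config(backbone = bb, sensor_dim = 2, use_sensor = FALSE,
                                  head_hidden = 2, heads = "cls"))
  expect_equal(length(m32$params[["stem.W"]]) + length(m32$params[["stem.g"]]) +
                 length(m32$params[["stem.b"]]), 928)
})

test_that("static MAC counter matches closed forms and the instrumented enumeration oracle", {
  # stem at 224: 864 multiplies per output pixel on a 112x112 grid
  cfg_full <- model_config(backbone = backbone_config("full"))
  stem_macs <- 27 * 32 * 112 * 112
  expect_equal(stem_macs, 10838016)
  # halving the input resolution quarters every convolution's MACs
  cfg_img <- model_config(backbone = backbone_config("full"), use_sensor = FALSE)
  # 192 px halves to 96 px with even sizes throughout, so the scaling is exact
  m_hi <- count_macs(cfg_img, 192)
  m_lo <- count_macs(cfg_img, 96)
  head_fc <- sum(vapply(c(4, 1, 1), function(o) 1280 * cfg_img$head_hidden +
                          cfg_img$head_hidden * o, 0))
  # separate the resolution-invariant SE gating and head terms
  bb <- cfg_img$backbone
  se_total <- sum(vapply(treefusion:::backbone_blocks(bb),
                         function(b) 2 * b$cmid * b$sq, 0))
  expect_equal((m_hi - head_fc - se_total) / 4, m_lo - head_fc - se_total,
               tolerance = 1e-6)

  # brute-force enumeration on a toy 8x8 configuration
  stages <- data.frame(expand = c(1, 6), kernel = c(3, 3), stride = c(1, 2),
                       out_ch = c(4, 6), repeats = c(1, 1))
  bb_toy <- custom_backbone_config(4, stages, 10, 8)
  cfg_toy <- model_config(backbone = bb_toy, sensor_dim = 5, sensor_hidden = 7,
                          sensor_embed = 4, head_hidden = 6)
  expect_equal(count_macs(cfg_toy), naive_model_macs(cfg_toy))
})

test_that("backbone forward is shape-correct, order-preserving and deterministic", {
  m <- micro_model(seed = 8)
  imgs <- random_images(3, 16, seed = 3)
  fm <- treefusion:::images_to_fmap(imgs)
  r1 <- treefusion:::forward_backbone(m, fm, training = FALSE)
  r2 <- treefusion:::forward_backbone(m, fm, training = FALSE)
  expect_identical(r1$emb, r2$emb)            # bit-identical in evaluation mode
  expect_equal(dim(r1$emb), c(3, 12))
  # order preserved: single-image forward equals the batch row
  for (i in 1:3) {
    ri <- treefusion:::forward_backbone(m, treefusion:::images_to_fmap(imgs[i]))
    expect_equal(as.numeric(ri$emb), as.numeric(r1$emb[i, ]), tolerance = 1e-12)
  }
  # wrong resolution is rejected
  expect_error(treefusion:::forward_backbone(m, treefusion:::images_to_fmap(
    random_images(1, 8))), "resolution")
})

test_that("reference configuration: 1280-wide embedding and 7x7 pre-pool map at 224", {
  cfg <- model_config(backbone = backbone_config("full"))
  bb <- cfg$backbone
  h <- treefusion:::conv_out_size(224, 3, 2, 1)
  for (b in treefusion:::backbone_blocks(bb))
    h <- treefusion:::conv_out_size(h, b$k, b$stride, b$k %/% 2)
  expect_equal(h, 7)                           # cumulative stride 32
  expect_equal(bb$head_ch, 1280)
})
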