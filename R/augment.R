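#' Training-time image augmentation
#'
#' Random area crop (resized back to the input resolution), horizontal flip
#' with probability 1/2, and brightness/contrast scaling by factors drawn
#' from `U[1-b, 1+b]` / `U[1-c, 1+c]`. Deterministic under a fixed seed;
#' with a full-frame crop, flip disabled and both perturbations at zero the
#' transform is the identity. Augmentation is applied only in training
#' mode — evaluation uses the raw image.
#'
#' @param img `[H, W, 3]` array in `[0, 1]`.
#' @param seed optional integer seed.
#' @param crop_scale range of the crop area as a fraction of the image.
#' @param flip_prob probability of a horizontal flip.
#' @param brightness,contrast half-widths of the factor ranges (0.2 means
#'   +/- 20%).
#' @return augmented `[H, W, 3]` array in `[0, 1]`.
#' @export
augment_image <- function(img, seed = NULL, crop_scale = c(0.8, 1.0),
                          flip_prob = 0.5, brightness = 0.2, contrast = 0.2) {
  run <- function() {
    H <- dim(img)[1]; W <- dim(img)[2]
    area <- runif(1, crop_scale[1], crop_scale[2])
    side_h <- max(1L, round(H * sqrt(area)))
    side_w <- max(1L, round(W * sqrt(area)))
    y0 <- sample.int(H - side_h + 1L, 1L)
    x0 <- sample.int(W - side_w + 1L, 1L)
    out <- img[y0:(y0 + side_h - 1L), x0:(x0 + side_w - 1L), , drop = FALSE]
    out <- bilinear_resize(out, H, W)
    if (runif(1) < flip_prob) out <- out[, rev(seq_len(W)), , drop = FALSE]
    bf <- runif(1, 1 - brightness, 1 + brightness)
    cf <- runif(1, 1 - contrast, 1 + contrast)
    out <- out * bf
    m <- mean(out)
    out <- (out - m) * cf + m
    clamp(out, 0, 1)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
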