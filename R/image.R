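#' Load an RGB image, optionally applying a companion binary mask
#'
#' Reads a PNG into an `[H, W, 3]` array in `[0, 1]`. If a file with the
#' same basename plus `".mask.png"` exists (or `mask_path` is given), its
#' nonzero pixels mark the foreground and background pixels are set to a
#' constant fill before any resizing, emulating background-suppressed
#' input.
#'
#' @param path PNG file path.
#' @param mask_path optional explicit mask path.
#' @param fill background fill value in `[0, 1]`.
#' @return `[H, W, 3]` array.
#' @export
load_image <- function(path, mask_path = NULL, fill = 0) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (is.null(mask_path)) {
    cand <- sub("\\.png$", ".mask.png", path, ignore.case = TRUE)
    if (cand != path && file.exists(cand)) mask_path <- cand
  }
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    img <- apply_mask(img, m > 0, fill)
  }
  img
}

#' Suppress the background of an image with a binary mask
#'
#' @param img `[H, W, 3]` array.
#' @param mask logical `[H, W]` matrix, `TRUE` on the foreground.
#' @param fill background value.
#' @return the masked image.
#' @export
apply_mask <- function(img, mask, fill = 0) {
  stopifnot(all(dim(mask) == dim(img)[1:2]))
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[!mask] <- fill; img[, , ch] <- pl
  }
  img
}

#' Bilinear resize of an RGB image
#'
#' @param img `[H, W, 3]` array.
#' @param h,w target size.
#' @return `[h, w, 3]` array.
#' @export
bilinear_resize <- function(img, h, w) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H == h && W == w) return(img)
  if (length(dim(img)) == 3 && dim(img)[3] == 3)
    return(cpp_bilinear_resize(img, H, W, h, w))
  sy <- (seq_len(h) - 0.5) * H / h - 0.5
  sx <- (seq_len(w) - 0.5) * W / w - 0.5
  y0 <- clamp(floor(sy), 0, H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- clamp(floor(sx), 0, W - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- clamp(sy - y0, 0, 1); fx <- clamp(sx - x0, 0, 1)
  out <- array(0, dim = c(h, w, 3))
  iy0 <- y0 + 1; iy1 <- y1 + 1; ix0 <- x0 + 1; ix1 <- x1 + 1
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  for (ch in 1:3) {
    pl <- img[, , ch]
    a <- pl[iy0, ix0]; b <- pl[iy0, ix1]
    cc <- pl[iy1, ix0]; d <- pl[iy1, ix1]
    top <- a * (1 - wx) + b * wx
    bot <- cc * (1 - wx) + d * wx
    out[, , ch] <- top * (1 - wy) + bot * wy
  }
  out
}

#' Per-channel normalization statistics of a training image set
#'
#' Pixel values are assumed in `[0, 1]`; mean and sd are estimated per
#' channel over all pixels of all images and stored with the checkpoint so
#' inference applies the identical transform.
#'
#' @param images list of `[H, W, 3]` arrays.
#' @return list with `mean` and `sd` (length-3 each).
#' @export
image_channel_stats <- function(images) {
  sums <- c(0, 0, 0); sqs <- c(0, 0, 0); npx <- 0
  for (img in images) {
    for (ch in 1:3) {
      sums[ch] <- sums[ch] + sum(img[, , ch])
      sqs[ch] <- sqs[ch] + sum(img[, , ch]^2)
    }
    npx <- npx + prod(dim(img)[1:2])
  }
  m <- sums / npx
  v <- pmax(sqs / npx - m^2, 1e-8)
  list(mean = m, sd = sqrt(v))
}

#' Standardize an image with per-channel statistics
#'
#' @param img `[H, W, 3]` array in `[0, 1]`.
#' @param stats from [image_channel_stats()].
#' @return the standardized array.
#' @export
normalize_image <- function(img, stats) {
  for (ch in 1:3)
    img[, , ch] <- (img[, , ch] - stats$mean[ch]) / stats$sd[ch]
  img
}
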