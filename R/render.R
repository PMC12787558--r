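# Procedural tree renderer. Images emulate background-suppressed field
# photographs: a black background, a tapered trunk, and an elliptical canopy
# of filled blobs. The health signal enters only through the documented
# visual channels: canopy hue shifts brown-ward with the visual latent's
# leaf-color deviation, the foreground fill fraction tracks crown density,
# and the count of dark damage patches tracks bark damage.

HEALTHY_GREEN <- c(0.20, 0.55, 0.16)
STRESSED_BROWN <- c(0.45, 0.36, 0.12)
TRUNK_BROWN <- c(0.30, 0.21, 0.12)
DAMAGE_DARK <- c(0.08, 0.05, 0.03)

#' Render one synthetic tree to an RGB array
#'
#' Deterministic for a given (tree row, seed): the same inputs produce a
#' bit-identical image.
#'
#' @param tree one-row data.frame from [sample_population()] (render
#'   parameters `fill_frac`, `hue_mix`, `damage_n`, `trunk_w` populated).
#' @param cfg a [generator_config()] (resolution and render jitter).
#' @param seed integer seed for the appearance randomness.
#' @return `[res, res, 3]` array in `[0, 1]`.
#' @export
render_tree <- function(tree, cfg, seed = cfg$seed) {
  res <- cfg$resolution
  with_seed(derive_seed(seed, "render", tree$tree_id), {
    img <- array(0, dim = c(res, res, 3))
    px <- (col(matrix(0, res, res)) - 0.5) / res   # x in (0,1)
    py <- (row(matrix(0, res, res)) - 0.5) / res   # y in (0,1), down
    cy <- 0.36
    cwn <- clamp(tree$Canopy_Width_m / 10, 0.25, 1)
    rx <- 0.42 * cwn
    ry <- 0.9 * rx + 0.05

    # trunk: tapered rectangle from canopy center to the base
    tw <- tree$trunk_w
    trunk <- py >= cy & py <= 0.93 &
      abs(px - 0.5) <= tw / 2 * (1 + 1.2 * (py - cy))
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[trunk] <- TRUNK_BROWN[ch]; img[, , ch] <- pl
    }

    # canopy: blobs inside the ellipse; count tracks the fill fraction
    base_col <- HEALTHY_GREEN + tree$hue_mix * (STRESSED_BROWN - HEALTHY_GREEN)
    nb <- round(15 + 160 * tree$fill_frac)
    theta <- runif(nb, 0, 2 * pi)
    rad <- sqrt(runif(nb))
    bx <- 0.5 + rad * rx * cos(theta)
    by <- cy + rad * ry * sin(theta)
    rb <- (0.05 + 0.06 * runif(nb)) * (rx + ry)
    shade <- 1 + rnorm(nb, 0, 2 * cfg$render_jitter)
    for (b in seq_len(nb)) {
      mask <- (px - bx[b])^2 + (py - by[b])^2 <= rb[b]^2
      if (!any(mask)) next
      colb <- clamp(base_col * shade[b], 0, 1)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[mask] <- colb[ch]; img[, , ch] <- pl
      }
    }

    # dark damage patches on canopy and upper trunk
    nd <- tree$damage_n
    if (nd > 0) {
      dx <- 0.5 + runif(nd, -0.8, 0.8) * rx
      dy <- cy + runif(nd, -0.4, 1.2) * ry
      rd <- runif(nd, 0.015, 0.035)
      for (b in seq_len(nd)) {
        mask <- (px - dx[b])^2 + (py - dy[b])^2 <= rd[b]^2
        fg <- mask & (img[, , 2] > 0 | img[, , 1] > 0)  # only over foreground
        if (!any(fg)) next
        for (ch in 1:3) {
          pl <- img[, , ch]; pl[fg] <- DAMAGE_DARK[ch]; img[, , ch] <- pl
        }
      }
    }

    # pixel-level appearance noise on the foreground
    if (cfg$render_jitter > 0) {
      fg <- img[, , 1] + img[, , 2] + img[, , 3] > 0
      nfg <- sum(fg)
      if (nfg > 0) {
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[fg] <- clamp(pl[fg] + rnorm(nfg, 0, cfg$render_jitter), 0, 1)
          img[, , ch] <- pl
        }
      }
    }
    img
  })
}

#' Render every tree of a population
#'
#' @param pop a [sample_population()] result.
#' @param cfg a [generator_config()].
#' @return named list of `[res, res, 3]` arrays.
#' @export
render_population <- function(pop, cfg) {
  out <- lapply(seq_len(nrow(pop)), function(i) render_tree(pop[i, ], cfg))
  names(out) <- pop$tree_id
  out
}

#' Fraction of non-background pixels in a rendered image
#'
#' @param img `[H, W, 3]` array on a black background.
#' @return fraction in `[0, 1]`.
#' @export
foreground_fraction <- function(img) {
  mean(img[, , 1] + img[, , 2] + img[, , 3] > 0)
}
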