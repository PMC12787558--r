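#' Configure the MBConv image backbone
#'
#' The `"full"` profile is the canonical compact seven-stage layout: a 3x3
#' stride-2 stem with 32 channels; stages (expansion, kernel, stride,
#' output channels, repeats) = (1,3,1,16,1), (6,3,2,24,2), (6,5,2,40,2),
#' (6,3,2,80,3), (6,5,1,112,3), (6,5,2,192,4), (6,3,1,320,1); and a 1x1
#' head convolution to a 1280-wide pooled embedding, at 224x224 input
#' (cumulative stride 32, so the pre-pool map is 7x7). The `"tiny"` profile
#' applies a 0.25 width multiplier, caps all repeats at 1 and runs at 96x96;
#' it is intended for CPU-scale experiments and satisfies the same
#' structural invariants.
#'
#' @param profile `"full"` or `"tiny"`.
#' @param use_se keep the squeeze-and-excitation gates (`FALSE` gives the
#'   no-SE ablation variant).
#' @return object of class `tf_backbone_config`.
#' @export
backbone_config <- function(profile = c("full", "tiny"), use_se = TRUE) {
  profile <- match.arg(profile)
  stages <- data.frame(
    expand = c(1, 6, 6, 6, 6, 6, 6),
    kernel = c(3, 3, 5, 3, 5, 5, 3),
    stride = c(1, 2, 2, 2, 1, 2, 1),
    out_ch = c(16, 24, 40, 80, 112, 192, 320),
    repeats = c(1, 2, 2, 3, 3, 4, 1))
  if (profile == "full") {
    cfg <- custom_backbone_config(32, stages, 1280, 224, use_se)
  } else {
    m <- 0.25
    round_ch <- function(c) pmax(4L, as.integer(round(c * m)))
    stages$out_ch <- round_ch(stages$out_ch)
    stages$repeats <- rep(1L, nrow(stages))
    cfg <- custom_backbone_config(round_ch(32), stages, round_ch(1280), 96, use_se)
  }
  cfg$profile <- profile
  cfg
}

#' Build a backbone configuration from an explicit stage table
#'
#' Used by [backbone_config()] and by toy configurations in tests.
#'
#' @param stem_ch stem output channels (3x3 stride-2 convolution).
#' @param stages data.frame with columns `expand`, `kernel`, `stride`,
#'   `out_ch`, `repeats`.
#' @param head_ch width of the 1x1 head convolution / pooled embedding.
#' @param resolution input image side length (square input).
#' @param use_se keep squeeze-and-excitation gates.
#' @param se_ratio squeeze width as a fraction of each block's input channels.
#' @export
custom_backbone_config <- function(stem_ch, stages, head_ch, resolution,
                                   use_se = TRUE, se_ratio = 0.25) {
  stopifnot(all(c("expand", "kernel", "stride", "out_ch", "repeats") %in% names(stages)))
  stopifnot(all(stages$kernel %in% c(3, 5)), all(stages$stride %in% c(1, 2)),
            all(stages$expand >= 1), all(stages$repeats >= 1))
  structure(list(stem_ch = as.integer(stem_ch), stages = stages,
                 head_ch = as.integer(head_ch), resolution = as.integer(resolution),
                 use_se = isTRUE(use_se), se_ratio = se_ratio,
                 bn_eps = 1e-3, bn_momentum = 0.1, profile = "custom"),
            class = "tf_backbone_config")
}

# Expand the stage table into one entry per MBConv block. Within a stage,
# only the first block carries the stage stride and channel change.
backbone_blocks <- function(bb) {
  blocks <- list()
  cin <- bb$stem_ch
  for (s in seq_len(nrow(bb$stages))) {
    st <- bb$stages[s, ]
    for (r in seq_len(st$repeats)) {
      stride <- if (r == 1) st$stride else 1L
      bin <- if (r == 1) cin else st$out_ch
      cmid <- as.integer(bin * st$expand)
      blocks[[length(blocks) + 1]] <- list(
        cin = as.integer(bin), cout = as.integer(st$out_ch),
        k = as.integer(st$kernel), stride = as.integer(stride),
        expand = as.integer(st$expand), cmid = cmid,
        sq = max(1L, as.integer(floor(bin * bb$se_ratio))),
        residual = stride == 1 && bin == st$out_ch)
    }
    cin <- st$out_ch
  }
  blocks
}

#' Configure the full multimodal multi-task model
#'
#' Couples the image backbone with a two-layer sensor MLP
#' (`sensor_dim -> sensor_hidden -> sensor_embed`, SiLU between),
#' concatenation fusion (sensor block first), and up to three task heads
#' (`FC -> ReLU -> FC`): a 4-class softmax health classifier and two linear
#' gas-regression heads with fully independent parameters.
#'
#' @param backbone a [backbone_config()].
#' @param sensor_dim width of the encoded sensor vector (see
#'   [encoded_width()]); 30 under the reference schema.
#' @param sensor_hidden,sensor_embed sensor MLP widths (default 64 and 32).
#' @param head_hidden hidden width shared by the three heads; default 344
#'   for the full profile (sized so the complete reference model holds
#'   5.4 M trainable parameters, see [head_width_for_budget()]) and 64
#'   otherwise.
#' @param n_classes number of health classes (4).
#' @param loss_weights named weights (`cls`, `o2`, `co2`) of the multi-task
#'   objective; the reference setting 0.4/0.3/0.3 sums to 1.
#' @param use_image,use_sensor modality switches for ablation variants.
#' @param heads character subset of `c("cls","o2","co2")` to instantiate.
#' @param seed integer seed for weight initialization.
#' @return object of class `tf_model_config`.
#' @export
model_config <- function(backbone = backbone_config("full"),
                         sensor_dim = encoded_width(default_sensor_schema()),
                         sensor_hidden = 64, sensor_embed = 32,
                         head_hidden = NULL, n_classes = 4,
                         loss_weights = c(cls = 0.4, o2 = 0.3, co2 = 0.3),
                         use_image = TRUE, use_sensor = TRUE,
                         heads = c("cls", "o2", "co2"), seed = 1) {
  stopifnot(inherits(backbone, "tf_backbone_config"))
  stopifnot(use_image || use_sensor)
  heads <- match.arg(heads, several.ok = TRUE)
  if (is.null(head_hidden))
    head_hidden <- if (identical(backbone$profile, "full")) 344L else 64L
  stopifnot(all(c("cls", "o2", "co2") %in% names(loss_weights)),
            all(loss_weights >= 0))
  fusion_dim <- (if (use_sensor) sensor_embed else 0L) +
    (if (use_image) backbone$head_ch else 0L)
  structure(list(backbone = backbone,
                 sensor_dim = as.integer(sensor_dim),
                 sensor_hidden = as.integer(sensor_hidden),
                 sensor_embed = as.integer(sensor_embed),
                 head_hidden = as.integer(head_hidden),
                 n_classes = as.integer(n_classes),
                 loss_weights = loss_weights[c("cls", "o2", "co2")],
                 use_image = use_image, use_sensor = use_sensor,
                 heads = heads, fusion_dim = as.integer(fusion_dim),
                 seed = as.integer(seed)),
            class = "tf_model_config")
}

#' Verify (and minimally adjust) the head width against a parameter budget
#'
#' The head hidden width is the one free dimension left by the architecture
#' description; this utility checks that the configured width makes the
#' total trainable parameter count round to the target (in millions, one
#' decimal) and, if not, returns the admissible width closest to the
#' configured one.
#'
#' @param cfg a [model_config()].
#' @param target_millions parameter budget in millions (default 5.4).
#' @return integer head width.
#' @export
head_width_for_budget <- function(cfg, target_millions = 5.4) {
  total_for <- function(h) {
    cfg$head_hidden <- as.integer(h)
    count_params(cfg)
  }
  h0 <- cfg$head_hidden
  if (round(total_for(h0) / 1e6, 1) == target_millions) return(h0)
  for (d in seq_len(400)) {
    for (h in c(h0 - d, h0 + d)) {
      if (h >= 1 && round(total_for(h) / 1e6, 1) == target_millions)
        return(as.integer(h))
    }
  }
  stopf("no head width within +/-400 of %d meets a %.1fM budget", h0, target_millions)
}
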