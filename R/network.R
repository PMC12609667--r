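# Network assembly: spatial path (3 stages), context path (ResNet-18 backbone
# with attention refinement at 1/16 and 1/32 plus a global-pooling branch),
# feature fusion at 1/8, and the x8 upsampling head. Four variants cover the
# ablation grid: the baseline uses stride-2 convolutions and bilinear
# upsampling; "dwcm" swaps the spatial path for wavelet downsampling stages;
# "fum" swaps the upsamplers for dynamic-offset sampling; "wavebisenet" uses
# both.

#' Network configuration
#'
#' @param num_classes number of output classes (>= 2; default 2:
#'   background / nanowire).
#' @param input_size expected input `(H, W)`; inputs must have spatial
#'   dimensions divisible by 32 but need not match this value.
#' @param spatial_channels channel widths of the three spatial-path stages
#'   (defaults `c(64, 128, 256)`).
#' @param ffm_channels fused channel width at 1/8 scale (default 256).
#' @param backbone `"resnet18_random"` (He-initialized in-package backbone) or
#'   `"resnet18_pretrained"` (requires `backbone_weights`, a saved state dict).
#' @param variant one of `"wavebisenet"`, `"bisenetv1"`, `"bisenetv1+dwcm"`,
#'   `"bisenetv1+fum"`.
#' @param width_mult multiplier applied to every channel width (rounded to a
#'   multiple of 4, minimum 4); used for desk-scale training.
#' @param backbone_weights optional path to a backbone state dict (RDS).
#' @return A `wbs_network_config` list.
#' @export
network_config <- function(num_classes = 2L,
                           input_size = c(512L, 512L),
                           spatial_channels = c(64L, 128L, 256L),
                           ffm_channels = 256L,
                           backbone = c("resnet18_random",
                                        "resnet18_pretrained"),
                           variant = c("wavebisenet", "bisenetv1",
                                       "bisenetv1+dwcm", "bisenetv1+fum"),
                           width_mult = 1,
                           backbone_weights = NULL) {
  backbone <- match.arg(backbone)
  variant <- match.arg(variant)
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 spatial_channels = as.integer(spatial_channels),
                 ffm_channels = as.integer(ffm_channels),
                 backbone = backbone, variant = variant,
                 width_mult = width_mult,
                 backbone_weights = backbone_weights),
            class = "wbs_network_config")
}

# Scale a channel count by the width multiplier (multiple of 4, minimum 4).
scale_ch <- function(c, wm) as.integer(max(4, round(c * wm / 4) * 4))

variant_has <- function(variant, part) {
  switch(variant,
         wavebisenet = TRUE,
         bisenetv1 = FALSE,
         `bisenetv1+dwcm` = part == "dwcm",
         `bisenetv1+fum` = part == "fum",
         stop("unknown variant: ", variant, call. = FALSE))
}

#' Build a segmentation network
#'
#' @param cfg a [network_config()].
#' @return A trainable `wbs_module` with the configuration attached as
#'   `$config`; run it with [network_forward()] / [predict_mask()].
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "wbs_network_config"))
  wm <- cfg$width_mult
  sp <- vapply(cfg$spatial_channels, scale_ch, integer(1), wm = wm)
  base <- scale_ch(64L, wm)
  cf <- scale_ch(cfg$ffm_channels, wm)
  head_ch <- scale_ch(128L, wm)
  use_dwcm <- variant_has(cfg$variant, "dwcm")
  use_fum <- variant_has(cfg$variant, "fum")

  m <- new_module(sprintf("%s(wm=%g)", cfg$variant, wm))
  m$config <- cfg
  m$use_fum <- use_fum

  if (use_dwcm) {
    m$children$sp1 <- nn_dwcm(3L, sp[1])
    m$children$sp2 <- nn_dwcm(sp[1], sp[2])
    m$children$sp3 <- nn_dwcm(sp[2], sp[3])
  } else {
    m$children$sp1 <- nn_conv_bn_relu(3L, sp[1], 3L, 2L, 1L)
    m$children$sp2 <- nn_conv_bn_relu(sp[1], sp[2], 3L, 2L, 1L)
    m$children$sp3 <- nn_conv_bn_relu(sp[2], sp[3], 3L, 2L, 1L)
  }
  m$children$backbone <- nn_resnet18(3L, base)
  if (identical(cfg$backbone, "resnet18_pretrained")) {
    if (is.null(cfg$backbone_weights) || !file.exists(cfg$backbone_weights)) {
      stop("backbone = 'resnet18_pretrained' requires backbone_weights, ",
           "a state-dict file saved with save_checkpoint()", call. = FALSE)
    }
    nn_load_state_dict(m$children$backbone, readRDS(cfg$backbone_weights))
  }
  m$children$arm16 <- nn_arm(4L * base)
  m$children$arm32 <- nn_arm(8L * base)
  m$children$gap_conv <- nn_conv_bn_relu(8L * base, 8L * base, 1L)
  m$children$head16 <- nn_conv_bn_relu(4L * base, head_ch, 3L, 1L, 1L)
  m$children$head32 <- nn_conv_bn_relu(8L * base, head_ch, 3L, 1L, 1L)
  if (use_fum) m$children$up32 <- nn_fum(head_ch, 4L)
  m$children$ffm <- nn_ffm(sp[3] + 2L * head_ch, cf)
  m$children$classifier <- nn_conv2d(cf, cfg$num_classes, 1L)
  if (use_fum) m$children$up_head <- nn_fum(cf, 8L)

  m$forward <- function(x, training = FALSE) {
    network_forward(m, x, training = training)
  }
  m
}

net_check_input <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (!nd %in% c(3L, 4L)) stop("image must be (H, W, 3[, N])", call. = FALSE)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop(sprintf(
      "spatial dims (%d, %d) must be divisible by 32; pad to (%d, %d)",
      d[1], d[2], 32 * ceiling(d[1] / 32), 32 * ceiling(d[2] / 32)),
      call. = FALSE)
  }
  if (nd == 3L) dim(x) <- c(d, 1L)
  list(x = x, nd = nd)
}

#' Forward pass of a segmentation network
#'
#' @param net a module from [build_network()].
#' @param image array `(H, W, 3)` or `(H, W, 3, N)`, values expected in
#'   `[0, 1]`; `H`, `W` divisible by 32.
#' @param training logical; batch statistics + gradient tape when `TRUE`.
#' @param return_features also return the intermediate spatial/context feature
#'   maps (values only).
#' @return Logits `(H, W, num_classes[, N])`, or a list with `logits` and
#'   `features` when `return_features = TRUE`.
#' @export
network_forward <- function(net, image, training = FALSE,
                            return_features = FALSE) {
  t4 <- net_check_input(ag_value(image))
  x <- if (is_node(image)) image else t4$x
  ch <- net$children

  s1 <- mod_forward(ch$sp1, x, training)
  s2 <- mod_forward(ch$sp2, s1, training)
  s3 <- mod_forward(ch$sp3, s2, training)

  fb <- mod_forward(ch$backbone, x, training)
  a16 <- mod_forward(ch$arm16, fb$f16, training)
  a32 <- mod_forward(ch$arm32, fb$f32, training)
  gctx <- mod_forward(ch$gap_conv, ag_gap(fb$f32), training)
  a32 <- ag_bcast_add(a32, gctx)
  h32 <- mod_forward(ch$head32, a32, training)
  u32 <- if (net$use_fum) {
    fum_forward(ch$up32, h32, training)
  } else {
    ag_upsample_bilinear(h32, 4L)
  }
  h16 <- mod_forward(ch$head16, a16, training)
  u16 <- ag_upsample_bilinear(h16, 2L)
  context <- ag_concat_c(list(u16, u32))

  fused <- ffm_forward(ch$ffm, s3, context, training)
  logits <- if (net$use_fum) {
    # dynamic x8 upsampling of the fused features, classification at full
    # resolution (offsets are predicted at the 1/8 feature grid)
    mod_forward(ch$classifier, fum_forward(ch$up_head, fused, training),
                training)
  } else {
    # baseline: classify at 1/8, bilinear x8 on the class scores
    ag_upsample_bilinear(mod_forward(ch$classifier, fused, training), 8L)
  }
  if (!is_node(logits) && t4$nd == 3L) {
    d <- dim(logits)
    dim(logits) <- d[1:3]
  }
  if (return_features) {
    feats <- lapply(list(spatial1 = s1, spatial2 = s2, spatial3 = s3,
                         context4 = fb$f4, context8 = fb$f8,
                         context16 = fb$f16, context32 = fb$f32,
                         context_fused = context, ffm = fused),
                    ag_value)
    return(list(logits = logits, features = feats))
  }
  logits
}

#' Predict a segmentation mask
#'
#' Argmax over the class axis; ties resolve to the lowest class index, so a
#' two-class tie yields background.
#'
#' @param net a module from [build_network()].
#' @param image input image array `(H, W, 3[, N])`.
#' @return Integer mask `(H, W[, N])` with values in `0 .. num_classes - 1`.
#' @export
predict_mask <- function(net, image) {
  logits <- with_no_grad(network_forward(net, image, training = FALSE))
  logits_to_mask(logits)
}

#' Convert logits to a label mask (lowest-index tie-break)
#' @param logits array `(H, W, nc[, N])`.
#' @return integer array `(H, W[, N])`.
#' @export
logits_to_mask <- function(logits) {
  d <- dim(logits)
  nd <- length(d)
  if (nd == 3L) dim(logits) <- c(d, 1L)
  d4 <- dim(logits)
  lm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d4[3])
  lab <- max.col(lm, ties.method = "first") - 1L
  out <- array(as.integer(lab), dim = c(d4[1], d4[2], d4[4]))
  if (nd == 3L) dim(out) <- d4[1:2]
  out
}
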