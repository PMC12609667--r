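# Architectural blocks: wavelet downsampling (DWCM), dynamic upsampling (FUM),
# attention refinement (ARM) and feature fusion (FFM), plus the ResNet-18
# basic blocks used by the context path.

#' Dual wavelet convolution module (DWCM)
#'
#' Downsampling stage that replaces a stride-2 convolution. The downsampling
#' block decomposes the input into the four Haar subbands (channel-wise
#' concatenation, `4*cin` channels at half resolution) and fuses them with a
#' 1x1 conv + BN + ReLU to `cout` channels. The extraction block then runs a
#' two-level wavelet analysis of the fused map: a 1x1 convolution mixes the
#' level-1 subband stack, a second analysis of the level-1 approximation is
#' mixed by its own 1x1 convolution, the level-2 result is synthesized back to
#' the level-1 grid and added into the approximation slot, and an inverse
#' transform returns to the block grid. A linear 1x1 convolution expands to
#' `4*cout` channels and a final 1x1 conv + BN + ReLU projects to `cout`.
#' The block halves the spatial dimensions exactly once; odd inputs are
#' edge-replication padded first.
#'
#' @param cin,cout input / output channel counts.
#' @return A trainable module; call it with [dwcm_forward()].
#' @export
nn_dwcm <- function(cin, cout) {
  m <- new_module(sprintf("dwcm(%d->%d)", cin, cout))
  m$cin <- cin
  m$cout <- cout
  m$children$down_fuse <- nn_conv_bn_relu(4L * cin, cout, k = 1L)
  m$children$ext_l1 <- nn_conv2d(4L * cout, 4L * cout, k = 1L)
  m$children$ext_l2 <- nn_conv2d(4L * cout, 4L * cout, k = 1L)
  m$children$ext_out <- nn_conv2d(cout, 4L * cout, k = 1L)
  m$children$proj <- nn_conv_bn_relu(4L * cout, cout, k = 1L)
  m$forward <- function(x, training = FALSE) {
    xp <- dwcm_downsample_block(m, x, training)
    xo <- dwcm_extract_block(m, xp, training)
    mod_forward(m$children$proj, xo, training)
  }
  m
}

#' DWCM wavelet feature downsampling block
#'
#' Haar decomposition of the input, channel-wise concatenation of the four
#' subbands (`4*cin` channels at half resolution), then 1x1 conv + BN + ReLU
#' to `cout` channels.
#'
#' @param m a module from [nn_dwcm()].
#' @param x feature map `(H, W, cin, N)` (`H`, `W` even after padding).
#' @param training logical; use batch statistics and record gradients.
#' @return fused feature map `(H/2, W/2, cout, N)`.
#' @export
dwcm_downsample_block <- function(m, x, training = FALSE) {
  v <- ag_value(x)
  d <- dim4(v)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    x <- if (is_node(x)) stop("odd input dims on the tape; pad upstream",
                              call. = FALSE) else pad_even(x)
  }
  mod_forward(m$children$down_fuse, ag_dwt(x), training)
}

#' DWCM wavelet feature extraction block
#'
#' Two-level wavelet analysis / synthesis of the fused map with per-level 1x1
#' channel mixing; returns `4*cout` channels at the same resolution as the
#' block input.
#'
#' @inheritParams dwcm_downsample_block
#' @param xp fused feature map from [dwcm_downsample_block()].
#' @return feature map `(H', W', 4*cout, N)`.
#' @export
dwcm_extract_block <- function(m, xp, training = FALSE) {
  C <- m$cout
  s1 <- ag_dwt(xp)
  y1 <- mod_forward(m$children$ext_l1, s1, training)
  ll1 <- ag_slice_c(y1, seq_len(C))
  s2 <- ag_dwt(ll1)
  y2 <- mod_forward(m$children$ext_l2, s2, training)
  rec2 <- ag_iwt(y2)
  merged <- ag_concat_c(list(ag_add(ll1, rec2),
                             ag_slice_c(y1, (C + 1):(4L * C))))
  recon <- ag_iwt(merged)
  mod_forward(m$children$ext_out, recon, training)
}

#' Run a DWCM block
#'
#' @inheritParams dwcm_downsample_block
#' @return feature map `(H/2, W/2, cout, N)`.
#' @export
dwcm_forward <- function(m, x, training = FALSE) {
  out <- m$forward(x, training)
  out
}

#' Flexible upsampling module (FUM)
#'
#' Content-aware upsampler. Two 1x1 convolutions predict, per channel group
#' and fine-grid position, a pair of sampling offsets gated as
#' `offset_range * sigmoid(a(x)) * b(x)` (an input-conditioned range gate with
#' fixed cap, 0.5 by default). Offsets are remapped channel-to-space by a
#' pixel-shuffle with the scale factor, added to the regular half-pixel
#' sampling grid, and the input is bilinearly sampled at the displaced grid
#' (border clamped). A 1x1 conv + BN + ReLU fuses channels. The offset branch
#' is zero-initialized, so an untrained FUM starts as exact bilinear
#' upsampling.
#'
#' @param channels input (= output) channel count.
#' @param scale integer upsampling factor `r >= 1`.
#' @param groups number of channel groups sharing an offset field; defaults to
#'   4 when divisible, else the largest of (2, 1) that divides `channels`.
#' @param offset_range cap of the offset gate, in coarse-pixel units.
#' @return A trainable module; call it with [fum_forward()].
#' @export
nn_fum <- function(channels, scale, groups = NULL, offset_range = 0.5) {
  if (scale < 1) stop("upsampling factor must be >= 1", call. = FALSE)
  if (is.null(groups)) {
    groups <- if (channels %% 4 == 0) 4L else if (channels %% 2 == 0) 2L else 1L
  }
  if (channels %% groups != 0) {
    stop("channels must be divisible by groups", call. = FALSE)
  }
  m <- new_module(sprintf("fum(%d, x%d, g=%d)", channels, scale, groups))
  m$channels <- as.integer(channels)
  m$scale <- as.integer(scale)
  m$groups <- as.integer(groups)
  m$offset_range <- offset_range
  noff <- 2L * m$groups * m$scale^2
  m$children$off_gate <- nn_conv2d(channels, noff, k = 1L)
  m$children$off_lin <- nn_conv2d(channels, noff, k = 1L, init = "zero")
  m$children$tail <- nn_conv_bn_relu(channels, channels, k = 1L)
  m$forward <- function(x, training = FALSE) fum_forward(m, x, training)
  m
}

#' Run a FUM block
#'
#' @param m a module from [nn_fum()].
#' @param x feature map `(H, W, channels, N)`.
#' @param training logical.
#' @return feature map `(H*r, W*r, channels, N)`.
#' @export
fum_forward <- function(m, x, training = FALSE) {
  v <- ag_value(x)
  d <- dim4(v)
  r <- m$scale
  g <- m$groups
  a <- mod_forward(m$children$off_gate, x, training)
  b <- mod_forward(m$children$off_lin, x, training)
  off <- ag_mul(ag_scalar_mul(ag_sigmoid(a), m$offset_range), b)
  off_fine <- ag_pixel_shuffle(off, r)        # (rH, rW, 2g, N)
  base <- base_grid(d[1], d[2], r, d[4])
  # offsets are in coarse-pixel units; normalized grid units are 2/size
  sc <- array(0, dim = c(d[1] * r, d[2] * r, 2, d[4]))
  sc[, , 1, ] <- 2 / d[2]
  sc[, , 2, ] <- 2 / d[1]
  cpg <- m$channels %/% g
  parts <- vector("list", g)
  for (j in seq_len(g)) {
    oj <- ag_slice_c(off_fine, c(2L * j - 1L, 2L * j))
    grid_j <- ag_add(base, ag_mul(oj, sc))
    xg <- ag_slice_c(x, (j - 1L) * cpg + seq_len(cpg))
    parts[[j]] <- ag_grid_sample(xg, grid_j)
  }
  samp <- if (g == 1) parts[[1]] else ag_concat_c(parts)
  mod_forward(m$children$tail, samp, training)
}

#' Attention refinement module (ARM)
#'
#' Channel attention: global average pooling, 1x1 convolution, batch
#' normalization and a sigmoid produce per-channel weights in (0, 1) that
#' rescale the input.
#'
#' @param C channel count.
#' @return A trainable module; call it with [arm_forward()].
#' @export
nn_arm <- function(C) {
  m <- new_module(sprintf("arm(%d)", C))
  m$children$conv <- nn_conv2d(C, C, k = 1L)
  m$children$bn <- nn_batchnorm(C)
  m$forward <- function(x, training = FALSE) arm_forward(m, x, training)
  m
}

#' Run an ARM block
#'
#' @param m a module from [nn_arm()].
#' @param x feature map `(H, W, C, N)`.
#' @param training logical.
#' @return feature map of the same shape, channel-reweighted.
#' @export
arm_forward <- function(m, x, training = FALSE) {
  w <- ag_sigmoid(mod_forward(m$children$bn,
                              mod_forward(m$children$conv, ag_gap(x), training),
                              training))
  ag_bcast_mul(x, w)
}

#' Feature fusion module (FFM)
#'
#' Concatenates the spatial- and context-path features (same spatial grid),
#' mixes them with a 3x3 conv + BN + ReLU to `cf` channels, computes channel
#' attention weights from the pooled result (1x1 conv, BN, sigmoid) and adds
#' the attention-scaled map back onto the pre-attention map:
#' `out = h + h * w`.
#'
#' @param cin_total channels of the concatenated input.
#' @param cf fused output channel count.
#' @return A trainable module; call it with [ffm_forward()].
#' @export
nn_ffm <- function(cin_total, cf) {
  m <- new_module(sprintf("ffm(%d->%d)", cin_total, cf))
  m$children$fuse <- nn_conv_bn_relu(cin_total, cf, k = 3L, pad = 1L)
  m$children$att_conv <- nn_conv2d(cf, cf, k = 1L)
  m$children$att_bn <- nn_batchnorm(cf)
  m$forward <- function(xs, training = FALSE) {
    ffm_forward(m, xs[[1]], xs[[2]], training)
  }
  m
}

#' Run an FFM block
#'
#' @param m a module from [nn_ffm()].
#' @param spatial,context feature maps sharing spatial dimensions.
#' @param training logical.
#' @return fused feature map with `cf` channels.
#' @export
ffm_forward <- function(m, spatial, context, training = FALSE) {
  ds <- dim4(ag_value(spatial))
  dc <- dim4(ag_value(context))
  if (!all(ds[c(1, 2, 4)] == dc[c(1, 2, 4)])) {
    stop("spatial and context features must share spatial dims and batch",
         call. = FALSE)
  }
  h <- mod_forward(m$children$fuse, ag_concat_c(list(spatial, context)),
                   training)
  w <- ag_sigmoid(mod_forward(m$children$att_bn,
                              mod_forward(m$children$att_conv, ag_gap(h),
                                          training),
                              training))
  ag_add(h, ag_bcast_mul(h, w))
}

# --- ResNet-18 style context backbone ---------------------------------------

nn_basic_block <- function(cin, cout, stride = 1L) {
  m <- new_module(sprintf("basic_block(%d->%d,s%d)", cin, cout, stride))
  m$children$conv1 <- nn_conv2d(cin, cout, 3L, stride, 1L, bias = FALSE)
  m$children$bn1 <- nn_batchnorm(cout)
  m$children$conv2 <- nn_conv2d(cout, cout, 3L, 1L, 1L, bias = FALSE)
  m$children$bn2 <- nn_batchnorm(cout)
  m$downsample <- (stride != 1L || cin != cout)
  if (m$downsample) {
    m$children$sc_conv <- nn_conv2d(cin, cout, 1L, stride, 0L, bias = FALSE)
    m$children$sc_bn <- nn_batchnorm(cout)
  }
  m$forward <- function(x, training = FALSE) {
    h <- ag_relu(mod_forward(m$children$bn1,
                             mod_forward(m$children$conv1, x, training),
                             training))
    h <- mod_forward(m$children$bn2,
                     mod_forward(m$children$conv2, h, training), training)
    sc <- if (m$downsample) {
      mod_forward(m$children$sc_bn,
                  mod_forward(m$children$sc_conv, x, training), training)
    } else x
    ag_relu(ag_add(h, sc))
  }
  m
}

# Returns features at 1/4, 1/8, 1/16 and 1/32 of the input resolution.
nn_resnet18 <- function(in_ch = 3L, base = 64L) {
  m <- new_module(sprintf("resnet18(base=%d)", base))
  m$children$stem_conv <- nn_conv2d(in_ch, base, 7L, 2L, 3L, bias = FALSE)
  m$children$stem_bn <- nn_batchnorm(base)
  m$children$layer1a <- nn_basic_block(base, base, 1L)
  m$children$layer1b <- nn_basic_block(base, base, 1L)
  m$children$layer2a <- nn_basic_block(base, 2L * base, 2L)
  m$children$layer2b <- nn_basic_block(2L * base, 2L * base, 1L)
  m$children$layer3a <- nn_basic_block(2L * base, 4L * base, 2L)
  m$children$layer3b <- nn_basic_block(4L * base, 4L * base, 1L)
  m$children$layer4a <- nn_basic_block(4L * base, 8L * base, 2L)
  m$children$layer4b <- nn_basic_block(8L * base, 8L * base, 1L)
  m$forward <- function(x, training = FALSE) {
    h <- ag_relu(mod_forward(m$children$stem_bn,
                             mod_forward(m$children$stem_conv, x, training),
                             training))
    h <- ag_maxpool(h, 3L, 2L, 1L)
    f4 <- mod_forward(m$children$layer1b,
                      mod_forward(m$children$layer1a, h, training), training)
    f8 <- mod_forward(m$children$layer2b,
                      mod_forward(m$children$layer2a, f4, training), training)
    f16 <- mod_forward(m$children$layer3b,
                       mod_forward(m$children$layer3a, f8, training), training)
    f32 <- mod_forward(m$children$layer4b,
                       mod_forward(m$children$layer4a, f16, training), training)
    list(f4 = f4, f8 = f8, f16 = f16, f32 = f32)
  }
  m
}
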