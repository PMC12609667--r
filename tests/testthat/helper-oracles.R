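# Independent brute-force oracles and small utilities shared by the tests.
# Every oracle here is a direct nested-loop implementation, kept free of the
# package's own vectorized/compiled code paths.

# Central-difference numerical gradient of a scalar function.
num_grad <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# Nested-loop single-level Haar analysis of one (H, W) matrix: each output
# pixel is the normalized dot product of a 2x2 block with the kernel.
oracle_hwt <- function(x, bank = haar_filter_bank()) {
  H <- nrow(x); W <- ncol(x)
  out <- list()
  for (nm in c("f_ll", "f_lh", "f_hl", "f_hh")) {
    f <- bank[[nm]]
    sb <- matrix(0, H / 2, W / 2)
    for (i in seq_len(H / 2)) {
      for (j in seq_len(W / 2)) {
        blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
        # accumulate in a fixed kernel order (row-wise) so the comparison
        # with the implementation can be exact, not just within tolerance
        sb[i, j] <- bank$norm * (f[1, 1] * blk[1, 1] + f[1, 2] * blk[1, 2] +
                                   f[2, 1] * blk[2, 1] + f[2, 2] * blk[2, 2])
      }
    }
    out[[sub("f_", "", nm)]] <- sb
  }
  out
}

# Nested-loop bilinear upsampling, half-pixel centers, border clamped.
oracle_bilinear <- function(x, r) {
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- array(0, c(H * r, W * r, dim(x)[3], dim(x)[4]))
  for (i in seq_len(H * r)) {
    for (j in seq_len(W * r)) {
      fy <- min(max((i - 0.5) / r - 0.5, 0), H - 1)
      fx <- min(max((j - 0.5) / r - 0.5, 0), W - 1)
      y0 <- floor(fy); x0 <- floor(fx)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      ay <- fy - y0; ax <- fx - x0
      out[i, j, , ] <- (1 - ay) * ((1 - ax) * x[y0 + 1, x0 + 1, , ] +
                                     ax * x[y0 + 1, x1 + 1, , ]) +
        ay * ((1 - ax) * x[y1 + 1, x0 + 1, , ] + ax * x[y1 + 1, x1 + 1, , ])
    }
  }
  out
}

# Naive per-pixel counting implementation of all reported metrics.
oracle_metrics <- function(pred, ref) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (ref[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (ref[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (ref[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (ref[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  total <- tp + tn + fp + fn
  iou_fg <- tp / (tp + fp + fn)
  iou_bg <- tn / (tn + fp + fn)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  po <- (tp + tn) / total
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  list(miou = (iou_fg + iou_bg) / 2, accuracy = po,
       f1 = 2 * p * r / (p + r), kappa = (po - pe) / (1 - pe),
       iou_fg = iou_fg, iou_bg = iou_bg)
}

# Naive 3x3 binary morphology; out-of-image neighbours ignored (erosion as if
# padded with 1, dilation as if padded with 0).
oracle_erode <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      v <- 1L
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > H || jj < 1 || jj > W) next
          if (m[ii, jj] == 0) v <- 0L
        }
      }
      out[i, j] <- v
    }
  }
  out
}

oracle_dilate <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      v <- 0L
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > H || jj < 1 || jj > W) next
          if (m[ii, jj] == 1) v <- 1L
        }
      }
      out[i, j] <- v
    }
  }
  out
}

oracle_opening <- function(m) oracle_dilate(oracle_erode(m))
oracle_closing <- function(m) oracle_erode(oracle_dilate(m))

# Make a batch-norm layer an exact identity in eval mode (gamma = 1, beta = 0,
# zero running mean, running variance compensating the stabilizer epsilon).
bn_make_identity <- function(bn) {
  bn$params$gamma$value[] <- 1
  bn$params$beta$value[] <- 0
  bn$running_mean[] <- 0
  bn$running_var[] <- 1 - bn$eps
  invisible(bn)
}

# A FUM whose offset branch is silenced and whose tail is an exact identity
# (in eval mode), i.e. plain bilinear upsampling followed by ReLU.
fum_degenerate <- function(channels, scale) {
  m <- nn_fum(channels, scale)
  m$children$off_lin$params$weight$value[] <- 0
  m$children$off_lin$params$bias$value[] <- 0
  m$children$tail$children$conv$params$weight$value <-
    wavebisenet:::conv_identity_weight(1L, channels, channels)
  bn_make_identity(m$children$tail$children$bn)
  m
}

# Deterministic tiny sample sets for training tests.
tiny_samples <- function(n, size = 32L, seed = 1L) {
  lapply(seq_len(n), function(i) {
    generate_sample(synthetic_config(
      image_size = c(size, size), n_wires = c(1L, 2L),
      wire_width_px = c(3, 4), curvature = 0.2, blur_sigma = 0.8,
      noise_sd = 5, illumination_gradient = 10, seed = seed * 1000L + i))
  })
}
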