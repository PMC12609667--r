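# Differentiable array operations. Feature maps are 4-d arrays (H, W, C, N).

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# --- elementwise -----------------------------------------------------------

ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va + vb, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va * vb, list(a, b), function(g) list(g * vb, g * va))
}

ag_scalar_mul <- function(x, s) {
  v <- ag_value(x)
  ag_op(v * s, list(x), function(g) list(g * s))
}

ag_relu <- function(x) {
  v <- ag_value(x)
  out <- v
  out[out < 0] <- 0
  ag_op(out, list(x), function(g) list(g * (v > 0)))
}

ag_sigmoid <- function(x) {
  v <- ag_value(x)
  s <- 1 / (1 + exp(-v))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

# --- broadcasting over space ----------------------------------------------
# w has dim (1, 1, C, N); broadcast over H and W.

expand_hw <- function(w, H, W) {
  d <- dim(w)
  array(rep(as.vector(w), each = H * W), dim = c(H, W, d[3], d[4]))
}

sum_hw <- function(g) {
  d <- dim4(g)
  array(colSums(matrix(g, d[1] * d[2], d[3] * d[4])), dim = c(1, 1, d[3], d[4]))
}

ag_bcast_mul <- function(x, w) {
  v <- ag_value(x); wv <- ag_value(w)
  d <- dim4(v)
  wf <- expand_hw(wv, d[1], d[2])
  ag_op(v * wf, list(x, w),
        function(g) list(g * wf, sum_hw(g * v)))
}

ag_bcast_add <- function(x, w) {
  v <- ag_value(x); wv <- ag_value(w)
  d <- dim4(v)
  ag_op(v + expand_hw(wv, d[1], d[2]), list(x, w),
        function(g) list(g, sum_hw(g)))
}

# Global average pool over H, W -> (1, 1, C, N).
ag_gap <- function(x) {
  v <- ag_value(x)
  d <- dim4(v)
  hw <- d[1] * d[2]
  out <- array(colMeans(matrix(v, hw, d[3] * d[4])), dim = c(1, 1, d[3], d[4]))
  ag_op(out, list(x),
        function(g) list(expand_hw(g, d[1], d[2]) / hw))
}

# --- channel concatenation / slicing ---------------------------------------

ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  ds <- lapply(vals, dim4)
  cs <- vapply(ds, function(d) d[3], numeric(1))
  d1 <- ds[[1]]
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(vals)) {
    out[, , at + seq_len(cs[i]), ] <- vals[[i]]
    at <- at + cs[i]
  }
  offs <- cumsum(c(0, cs))
  ag_op(out, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      g[, , offs[i] + seq_len(cs[i]), , drop = FALSE]
    })
  })
}

ag_slice_c <- function(x, idx) {
  v <- ag_value(x)
  d <- dim4(v)
  out <- v[, , idx, , drop = FALSE]
  ag_op(out, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[, , idx, ] <- g
    list(dx)
  })
}

# --- convolution ------------------------------------------------------------
# weight: (k, k, Cin, Cout); bias: length Cout or NULL.

ag_conv2d <- function(x, weight, bias = NULL, stride = 1L, pad = 0L) {
  v <- ag_value(x)
  wv <- ag_value(weight)
  bv <- if (is.null(bias)) NULL else ag_value(bias)
  d <- dim4(v)
  k <- dim(wv)[1]
  cin <- dim(wv)[3]; cout <- dim(wv)[4]
  stopifnot(cin == d[3])
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  wm <- matrix(wv, nrow = k * k * cin, ncol = cout)
  if (k == 1L && stride == 1L && pad == 0L && d[4] == 1L) {
    # single image, pointwise conv: (H, W, C, 1) is already an (H*W) x C
    # matrix in memory, so no patch extraction or transpose is needed
    cols <- v
    dim(cols) <- c(d[1] * d[2], d[3])
  } else {
    cols <- wbs_im2col(v, d[1], d[2], d[3], d[4], k, stride, pad)
  }
  om <- cols %*% wm
  if (!ag_enabled()) cols <- NULL  # only the backward pass needs the patches
  if (!is.null(bv)) om <- om + rep(bv, each = nrow(om))
  if (d[4] == 1L) {
    out <- om                      # (Ho, Wo, 1, cout) and (Ho, Wo, cout, 1)
    dim(out) <- c(Ho, Wo, cout, 1L)  # share the same memory layout
  } else {
    dim(om) <- c(Ho, Wo, d[4], cout)
    out <- aperm(om, c(1, 2, 4, 3))
  }
  om <- NULL
  parents <- list(x, weight, bias)
  need_dx <- is_node(x)
  ag_op(out, parents, function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), nrow = Ho * Wo * d[4], ncol = cout)
    dw <- array(crossprod(cols, gm), dim = dim(wv))
    db <- if (is.null(bv)) NULL else colSums(gm)
    dx <- NULL
    if (need_dx) {
      dcols <- tcrossprod(gm, wm)
      dx <- wbs_col2im(dcols, d[1], d[2], d[3], d[4], k, stride, pad)
    }
    list(dx, dw, db)
  })
}

# --- batch normalization ----------------------------------------------------
# gamma, beta: length-C vectors. `layer` is the owning module environment with
# buffers running_mean / running_var updated as a side effect in training.

ag_batchnorm <- function(x, gamma, beta, layer, training,
                         momentum = 0.1, eps = 1e-5) {
  v <- ag_value(x)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- dim4(v)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  if (d[4] == 1L) {
    xm <- v            # (H, W, C, 1) is already (H*W) x C column-major
    dim(xm) <- c(m, C)
  } else {
    xm <- matrix(aperm(v, c(1, 2, 4, 3)), m, C)
  }
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    if (isTRUE(getOption("wbs_bn_diag"))) {
      message(sprintf("BN %-28s m=%7d  |mu-rm|max=%9.3g  va/rv max=%9.3g min=%9.3g",
                      layer$type, m, max(abs(mu - layer$running_mean)),
                      max(va / pmax(layer$running_var, 1e-12)),
                      min(va / pmax(layer$running_var, 1e-12))))
    }
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    corr <- if (m > 1) m / (m - 1) else 1
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * va * corr
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  sd_ <- sqrt(va + eps)
  if (!ag_enabled()) {
    # inference fast path: fold the normalization into one affine transform
    # and overwrite in place to keep a single full-size temporary alive
    xm <- sweep(xm, 2, gv / sd_, "*")
    xm <- sweep(xm, 2, bv - gv * mu / sd_, "+")
    if (d[4] == 1L) {
      dim(xm) <- d
      return(xm)
    }
    dim(xm) <- c(d[1], d[2], d[4], C)
    return(aperm(xm, c(1, 2, 4, 3)))
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sd_, "/")
  xm <- NULL
  ym <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  out <- aperm(array(ym, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  ym <- NULL
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), m, C)
    dbeta <- colSums(gm)
    dgamma <- colSums(gm * xhat)
    dxhat <- sweep(gm, 2, gv, "*")
    if (training) {
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * xhat)
      dxm <- sweep(m * dxhat, 2, t1) - sweep(xhat, 2, t2, "*")
      dxm <- sweep(dxm, 2, m * sd_, "/")
    } else {
      dxm <- sweep(dxhat, 2, sd_, "/")
    }
    dx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

# --- pooling ----------------------------------------------------------------

ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  v <- ag_value(x)
  d <- dim4(v)
  r <- wbs_maxpool_fwd(v, d[1], d[2], d[3], d[4], k, stride, pad)
  ag_op(r$out, list(x), function(g) {
    dx <- wbs_maxpool_bwd(g, r$argmax, length(v))
    dim(dx) <- d
    list(dx)
  })
}

# --- pixel shuffle ----------------------------------------------------------
# (H, W, C*r^2, N) -> (H*r, W*r, C, N); input channel index (0-based) is
# j + r*i + r^2*c where i is the row offset and j the column offset.

ag_pixel_shuffle <- function(x, r) {
  v <- ag_value(x)
  d <- dim4(v)
  C <- d[3] %/% (r * r)
  stopifnot(C * r * r == d[3])
  v6 <- v
  dim(v6) <- c(d[1], d[2], r, r, C, d[4])
  out <- aperm(v6, c(4, 1, 3, 2, 5, 6))
  dim(out) <- c(d[1] * r, d[2] * r, C, d[4])
  ag_op(out, list(x), function(g) {
    dim(g) <- c(r, d[1], r, d[2], C, d[4])
    dx <- aperm(g, c(2, 4, 3, 1, 5, 6))
    dim(dx) <- d
    list(dx)
  })
}

# --- bilinear grid sampling -------------------------------------------------
# grid: (Ho, Wo, 2, N), slice 1 = x (width) and slice 2 = y (height), in
# normalized [-1, 1] coordinates with half-pixel centers; border clamping.

ag_grid_sample <- function(x, grid) {
  v <- ag_value(x)
  gv <- ag_value(grid)
  d <- dim4(v)
  dg <- dim4(gv)
  out <- wbs_grid_sample_fwd(v, gv, d[1], d[2], d[3], d[4], dg[1], dg[2])
  ag_op(out, list(x, grid), function(g) {
    r <- wbs_grid_sample_bwd(v, gv, g, d[1], d[2], d[3], d[4], dg[1], dg[2])
    list(r$dx, r$dgrid)
  })
}

# Regular upsampling grid in normalized coordinates (half-pixel centers):
# fine pixel i (1-based) maps to coarse pixel position (i - 0.5)/r - 0.5.
base_grid <- function(H, W, r, N) {
  Ho <- H * r; Wo <- W * r
  py <- (seq_len(Ho) - 0.5) / r - 0.5
  px <- (seq_len(Wo) - 0.5) / r - 0.5
  gy <- (2 * py + 1) / H - 1
  gx <- (2 * px + 1) / W - 1
  g <- array(0, dim = c(Ho, Wo, 2, N))
  g[, , 1, ] <- matrix(gx, Ho, Wo, byrow = TRUE)
  g[, , 2, ] <- matrix(gy, Ho, Wo)
  g
}

# Plain bilinear upsampling by integer factor r (half-pixel convention).
ag_upsample_bilinear <- function(x, r) {
  v <- ag_value(x)
  d <- dim4(v)
  ag_grid_sample(x, base_grid(d[1], d[2], r, d[4]))
}

# --- Haar wavelet analysis / synthesis as tape ops --------------------------
# Forward returns the four subbands concatenated channel-wise in the order
# (LL, LH, HL, HH): (H, W, C, N) -> (H/2, W/2, 4C, N). The transform is
# orthonormal, so the adjoint used in the backward pass is the inverse.

ag_dwt <- function(x, bank = haar_filter_bank()) {
  v <- ag_value(x)
  ag_op(dwt_stack(v, bank), list(x),
        function(g) list(iwt_stack(g, bank)))
}

ag_iwt <- function(x, bank = haar_filter_bank()) {
  v <- ag_value(x)
  ag_op(iwt_stack(v, bank), list(x),
        function(g) list(dwt_stack(g, bank)))
}
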