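# The differentiation engine: forward correctness of the compiled kernels and
# analytic gradients against central differences.

ns <- asNamespace("wavebisenet")

test_that("convolution forward matches a nested-loop oracle", {
  set.seed(5)
  x <- array(rnorm(6 * 7 * 2 * 2), c(6, 7, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  out <- ag_value(ns$ag_conv2d(x, ns$ag_param(w), ns$ag_param(b),
                               stride = 2L, pad = 1L))
  # direct cross-correlation with zero padding
  Ho <- 3; Wo <- 4
  for (n in 1:2) {
    for (co in 1:3) {
      for (i in 1:Ho) {
        for (j in 1:Wo) {
          acc <- b[co]
          for (kh in 1:3) {
            for (kw in 1:3) {
              h <- (i - 1) * 2 - 1 + kh
              wd <- (j - 1) * 2 - 1 + kw
              if (h >= 1 && h <= 6 && wd >= 1 && wd <= 7) {
                acc <- acc + sum(x[h, wd, , n] * w[kh, kw, , co])
              }
            }
          }
          expect_equal(out[i, j, co, n], acc, tolerance = 1e-12)
        }
      }
    }
  }
})

scalar_sq <- function(out) {
  ns$ag_op(sum(ag_value(out)^2), list(out),
           function(g) list(2 * ag_value(out) * g))
}

test_that("analytic gradients match central differences", {
  set.seed(9)
  tol <- 1e-6

  # convolution: input, weight, bias
  x <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
  b <- rnorm(4) * 0.1
  xn <- ns$new_node(x); wn <- ns$ag_param(w); bn <- ns$ag_param(b)
  node <- scalar_sq(ns$ag_conv2d(xn, wn, bn, 2L, 1L))
  ns$ag_backward(node)
  f <- function(v, which) {
    args <- list(x = x, w = w, b = b); args[[which]] <- v
    sum(ag_value(ns$ag_conv2d(ns$new_node(args$x), ns$ag_param(args$w),
                              ns$ag_param(args$b), 2L, 1L))^2)
  }
  expect_lt(max(abs(xn$grad - num_grad(function(v) f(v, "x"), x))), tol)
  expect_lt(max(abs(wn$grad - num_grad(function(v) f(v, "w"), w))), tol)
  expect_lt(max(abs(bn$grad - num_grad(function(v) f(v, "b"), b))), tol)

  # batch normalization (training statistics)
  xb <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  bnmod <- ns$nn_batchnorm(3L)
  xn <- ns$new_node(xb)
  node <- scalar_sq(ns$ag_batchnorm(xn, bnmod$params$gamma, bnmod$params$beta,
                                    bnmod, TRUE))
  ns$ag_backward(node)
  fn_bn <- function(v) {
    m <- ns$nn_batchnorm(3L)
    sum(ag_value(ns$ag_batchnorm(ns$new_node(v), m$params$gamma,
                                 m$params$beta, m, TRUE))^2)
  }
  expect_lt(max(abs(xn$grad - num_grad(fn_bn, xb))), 1e-5)

  # grid sampling: input and grid
  xs <- array(rnorm(4 * 5 * 2 * 2), c(4, 5, 2, 2))
  gr <- array(runif(6 * 7 * 2 * 2, -0.9, 0.9), c(6, 7, 2, 2))
  xn <- ns$new_node(xs); gn <- ns$new_node(gr)
  node <- scalar_sq(ns$ag_grid_sample(xn, gn))
  ns$ag_backward(node)
  expect_lt(max(abs(xn$grad - num_grad(function(v)
    sum(ag_value(ns$ag_grid_sample(ns$new_node(v), gr))^2), xs))), tol)
  expect_lt(max(abs(gn$grad - num_grad(function(v)
    sum(ag_value(ns$ag_grid_sample(ns$new_node(xs), ns$new_node(v)))^2),
    gr))), tol)

  # max pooling and pixel shuffle
  xp <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  xn <- ns$new_node(xp)
  node <- scalar_sq(ns$ag_maxpool(xn))
  ns$ag_backward(node)
  expect_lt(max(abs(xn$grad - num_grad(function(v)
    sum(ag_value(ns$ag_maxpool(ns$new_node(v)))^2), xp))), tol)

  xps <- array(rnorm(3 * 4 * 8 * 2), c(3, 4, 8, 2))
  xn <- ns$new_node(xps)
  node <- scalar_sq(ns$ag_pixel_shuffle(xn, 2L))
  ns$ag_backward(node)
  expect_lt(max(abs(xn$grad - num_grad(function(v)
    sum(ag_value(ns$ag_pixel_shuffle(ns$new_node(v), 2L))^2), xps))), tol)
})

test_that("pixel shuffle rearranges channels to space as documented", {
  # one coarse pixel, r = 2: channel j + r*i (0-based) lands at offset (i, j)
  x <- array(1:4, c(1, 1, 4, 1))
  out <- ag_value(ns$ag_pixel_shuffle(x, 2L))
  expect_equal(out[, , 1, 1], matrix(c(1, 3, 2, 4), 2, 2))
})

test_that("the fused segmentation loss gradient is exact", {
  set.seed(13)
  lg <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  mk <- array(sample(0:1, 32, TRUE), c(4, 4, 2))
  xn <- ns$new_node(lg)
  node <- ns$ag_seg_loss(xn, mk)
  ns$ag_backward(node)
  expect_lt(max(abs(xn$grad - num_grad(function(v)
    ag_value(ns$ag_seg_loss(ns$new_node(v), mk)), lg))), 1e-7)
  # and its value agrees with the user-facing combined loss
  expect_equal(node$value, as.numeric(combined_loss(lg, mk)), tolerance = 1e-12)
})

test_that("tape evaluation is disabled under with_no_grad", {
  x <- array(rnorm(8), c(2, 2, 2, 1))
  p <- ns$ag_param(array(rnorm(4), c(1, 1, 2, 2)))
  out <- ns$with_no_grad(ns$ag_conv2d(x, p, NULL))
  expect_false(ns$is_node(out))
})
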