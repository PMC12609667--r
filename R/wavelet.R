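# Orthonormal 2-D Haar analysis / synthesis used by the wavelet downsampling
# and feature-extraction blocks.

#' Orthonormal Haar filter bank
#'
#' Returns the four 2x2 Haar kernels: `f_ll` (low-pass approximation), `f_lh`
#' (horizontal detail), `f_hl` (vertical detail) and `f_hh` (diagonal detail),
#' together with the common normalization scalar. With `norm = 1/2` the four
#' flattened kernels are orthonormal, so analysis followed by synthesis is the
#' identity and subband energy equals input energy.
#'
#' @return An object of class `wbs_filter_bank`: a list with 2x2 matrices
#'   `f_ll`, `f_lh`, `f_hl`, `f_hh` (entries in `{-1, 1}`) and scalar `norm`.
#' @examples
#' bank <- haar_filter_bank()
#' K <- sapply(bank[c("f_ll", "f_lh", "f_hl", "f_hh")], as.vector) * bank$norm
#' crossprod(K)  # 4x4 identity
#' @export
haar_filter_bank <- function() {
  structure(list(
    f_ll = matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE),
    f_lh = matrix(c(-1, -1, 1, 1), 2, 2, byrow = TRUE),
    f_hl = matrix(c(-1, 1, -1, 1), 2, 2, byrow = TRUE),
    f_hh = matrix(c(1, -1, -1, 1), 2, 2, byrow = TRUE),
    norm = 0.5
  ), class = "wbs_filter_bank")
}

# Coerce (H,W) / (H,W,C) / (H,W,C,N) to 4-d and remember the original rank.
to4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array", call. = FALSE)
  nd <- length(d)
  if (nd == 2) dim(x) <- c(d, 1L, 1L)
  else if (nd == 3) dim(x) <- c(d, 1L)
  else if (nd != 4) stop("input must have 2, 3 or 4 dimensions", call. = FALSE)
  list(x = x, nd = nd)
}

from4d <- function(x, nd) {
  d <- dim(x)
  if (nd == 2) dim(x) <- d[1:2]
  else if (nd == 3) dim(x) <- d[1:3]
  x
}

check_even <- function(d) {
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("spatial dimensions must be even; pad with pad_even() first",
         call. = FALSE)
  }
}

# One analysis level on a 4-d array -> subbands stacked channel-wise
# in the order (LL, LH, HL, HH): (H, W, C, N) -> (H/2, W/2, 4C, N).
dwt_stack <- function(v, bank = haar_filter_bank()) {
  d <- dim4(v)
  check_even(d)
  ro <- seq(1, d[1], by = 2); re <- ro + 1
  co <- seq(1, d[2], by = 2); ce <- co + 1
  A <- v[ro, co, , , drop = FALSE]
  B <- v[ro, ce, , , drop = FALSE]
  Cc <- v[re, co, , , drop = FALSE]
  D <- v[re, ce, , , drop = FALSE]
  comb <- function(f) bank$norm * (f[1, 1] * A + f[1, 2] * B +
                                     f[2, 1] * Cc + f[2, 2] * D)
  out <- array(0, dim = c(d[1] / 2, d[2] / 2, 4 * d[3], d[4]))
  cidx <- seq_len(d[3])
  out[, , cidx, ] <- comb(bank$f_ll)
  out[, , cidx + d[3], ] <- comb(bank$f_lh)
  out[, , cidx + 2 * d[3], ] <- comb(bank$f_hl)
  out[, , cidx + 3 * d[3], ] <- comb(bank$f_hh)
  out
}

# Synthesis: (H2, W2, 4C, N) -> (2*H2, 2*W2, C, N). For the orthonormal bank
# this is both the exact inverse and the adjoint of dwt_stack().
iwt_stack <- function(s, bank = haar_filter_bank()) {
  d <- dim4(s)
  C <- d[3] %/% 4
  stopifnot(C * 4 == d[3])
  cidx <- seq_len(C)
  ll <- s[, , cidx, , drop = FALSE]
  lh <- s[, , cidx + C, , drop = FALSE]
  hl <- s[, , cidx + 2 * C, , drop = FALSE]
  hh <- s[, , cidx + 3 * C, , drop = FALSE]
  out <- array(0, dim = c(2 * d[1], 2 * d[2], C, d[4]))
  ro <- seq(1, 2 * d[1], by = 2); re <- ro + 1
  co <- seq(1, 2 * d[2], by = 2); ce <- co + 1
  pos <- function(kh, kw) {
    bank$norm * (bank$f_ll[kh, kw] * ll + bank$f_lh[kh, kw] * lh +
                   bank$f_hl[kh, kw] * hl + bank$f_hh[kh, kw] * hh)
  }
  out[ro, co, , ] <- pos(1, 1)
  out[ro, ce, , ] <- pos(1, 2)
  out[re, co, , ] <- pos(2, 1)
  out[re, ce, , ] <- pos(2, 2)
  out
}

#' Single-level Haar wavelet decomposition
#'
#' Decomposes a feature map into the four stride-2 subbands: approximation
#' `ll` and the horizontal / vertical / diagonal details `lh`, `hl`, `hh`.
#' Each subband is the valid, stride-2 cross-correlation of the input with
#' the corresponding normalized 2x2 kernel, so spatial dimensions halve
#' exactly. Spatial dimensions must be even; use [pad_even()] upstream for
#' odd sizes.
#'
#' @param x numeric array with dimensions `(H, W)`, `(H, W, C)` or
#'   `(H, W, C, N)`; `H` and `W` must be even.
#' @param bank a filter bank from [haar_filter_bank()].
#' @return An object of class `wbs_subbands`: list with arrays `ll`, `lh`,
#'   `hl`, `hh` (each at half the input resolution, same rank as the input)
#'   and the decomposition `level`.
#' @examples
#' x <- matrix(rnorm(16), 4, 4)
#' s <- hwt_decompose(x)
#' max(abs(iwt_reconstruct(s) - x)) < 1e-12
#' @export
hwt_decompose <- function(x, bank = haar_filter_bank()) {
  t4 <- to4d(x)
  st <- dwt_stack(t4$x, bank)
  C <- dim(st)[3] %/% 4
  cidx <- seq_len(C)
  pick <- function(i) from4d(st[, , cidx + (i - 1) * C, , drop = FALSE], t4$nd)
  structure(list(ll = pick(1), lh = pick(2), hl = pick(3), hh = pick(4),
                 level = 1L),
            class = "wbs_subbands")
}

#' Haar decomposition at a recorded level
#'
#' Identical arithmetic to [hwt_decompose()]; the level (1 or 2) is recorded
#' in the result. By convention the level-2 call takes the level-1 `ll`
#' subband as its input, implementing the cascaded decomposition of the
#' low-frequency branch.
#'
#' @inheritParams hwt_decompose
#' @param level decomposition level, 1 or 2.
#' @return A `wbs_subbands` object with the given `level`.
#' @export
dwt_level <- function(x, bank = haar_filter_bank(), level = 1L) {
  if (!level %in% c(1L, 2L)) {
    stop("unsupported decomposition depth: level must be 1 or 2", call. = FALSE)
  }
  s <- hwt_decompose(x, bank)
  s$level <- as.integer(level)
  s
}

#' Inverse Haar wavelet reconstruction
#'
#' Exact inverse of [hwt_decompose()] under the orthonormal bank: recombines
#' the four subbands into a feature map at twice the subband resolution.
#'
#' @param s a `wbs_subbands` object (or a plain list with `ll`, `lh`, `hl`,
#'   `hh` arrays of identical shape).
#' @param bank a filter bank from [haar_filter_bank()].
#' @return Numeric array with the rank of the subbands and doubled spatial
#'   dimensions.
#' @export
iwt_reconstruct <- function(s, bank = haar_filter_bank()) {
  dims <- lapply(s[c("ll", "lh", "hl", "hh")], dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("subband shapes differ", call. = FALSE)
  }
  t4 <- to4d(s$ll)
  d <- dim(t4$x)
  st <- array(0, dim = c(d[1], d[2], 4 * d[3], d[4]))
  cidx <- seq_len(d[3])
  st[, , cidx, ] <- t4$x
  st[, , cidx + d[3], ] <- to4d(s$lh)$x
  st[, , cidx + 2 * d[3], ] <- to4d(s$hl)$x
  st[, , cidx + 3 * d[3], ] <- to4d(s$hh)$x
  from4d(iwt_stack(st, bank), t4$nd)
}

#' Pad a feature map to even spatial dimensions by edge replication
#'
#' @param x array of rank 2-4, spatial dimensions first.
#' @return The input, padded on the bottom/right by replicating the last row
#'   and/or column when the corresponding dimension is odd.
#' @export
pad_even <- function(x) {
  t4 <- to4d(x)
  v <- t4$x
  d <- dim(v)
  if (d[1] %% 2 != 0) {
    v <- array(v[c(seq_len(d[1]), d[1]), , , , drop = FALSE],
               dim = c(d[1] + 1, d[2], d[3], d[4]))
    d <- dim(v)
  }
  if (d[2] %% 2 != 0) {
    v <- array(v[, c(seq_len(d[2]), d[2]), , , drop = FALSE],
               dim = c(d[1], d[2] + 1, d[3], d[4]))
  }
  from4d(v, t4$nd)
}
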