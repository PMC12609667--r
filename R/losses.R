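# Compound training objective: 0.5 * pixel cross-entropy + 0.5 * weighted
# Dice, computed from logits over the class axis.

#' Loss configuration
#'
#' @param ce_weight,dice_weight convex weights of the two terms (must sum
#'   to 1; defaults 0.5 / 0.5).
#' @param dice_smooth small positive smoothing constant preventing 0/0 on
#'   empty classes.
#' @param class_weighting `"inverse_frequency"` (default): Dice class weights
#'   proportional to inverse per-batch class frequency (Laplace-smoothed),
#'   normalized to sum 1; `"none"`: equal weights (macro Dice).
#' @return A `wbs_loss_config` list.
#' @export
loss_config <- function(ce_weight = 0.5, dice_weight = 0.5,
                        dice_smooth = 1e-6,
                        class_weighting = c("inverse_frequency", "none")) {
  class_weighting <- match.arg(class_weighting)
  if (abs(ce_weight + dice_weight - 1) > 1e-12) {
    stop("ce_weight + dice_weight must equal 1", call. = FALSE)
  }
  if (dice_smooth <= 0) stop("dice_smooth must be > 0", call. = FALSE)
  structure(list(ce_weight = ce_weight, dice_weight = dice_weight,
                 dice_smooth = dice_smooth, class_weighting = class_weighting),
            class = "wbs_loss_config")
}

# Reshape logits (H, W, nc[, N]) to an (npix, nc) matrix and the mask to an
# aligned integer vector; validates label range.
loss_flatten <- function(logits, mask, check = TRUE) {
  d <- dim(logits)
  if (length(d) == 3L) dim(logits) <- c(d, 1L)
  d4 <- dim(logits)
  nc <- d4[3]
  mv <- as.integer(round(as.vector(mask)))
  if (length(mv) != d4[1] * d4[2] * d4[4]) {
    stop("logits and mask shapes disagree", call. = FALSE)
  }
  if (check && (min(mv) < 0L || max(mv) >= nc)) {
    stop(sprintf("mask values must lie in 0..%d", nc - 1L), call. = FALSE)
  }
  lm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = nc)
  list(lm = lm, mv = mv, nc = nc)
}

softmax_rows <- function(lm) {
  mx <- do.call(pmax, c(as.data.frame(lm), list(na.rm = FALSE)))
  e <- exp(lm - mx)
  e / rowSums(e)
}

dice_class_weights <- function(mv, nc, class_weighting) {
  if (class_weighting == "none") return(rep(1 / nc, nc))
  ycount <- tabulate(mv + 1L, nbins = nc)
  freq <- (ycount + 1) / (length(mv) + nc)  # Laplace-smoothed frequency
  w <- 1 / freq
  w / sum(w)
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over all pixels of the negative log softmax probability of the true
#' class.
#'
#' @param logits array `(H, W, nc[, N])`.
#' @param mask integer array `(H, W[, N])` with labels in `0 .. nc - 1`.
#' @return nonnegative scalar.
#' @examples
#' lg <- array(0, c(2, 2, 2))       # uniform logits
#' cross_entropy(lg, matrix(0L, 2, 2))  # log(2)
#' @export
cross_entropy <- function(logits, mask) {
  f <- loss_flatten(logits, mask)
  mx <- do.call(pmax, as.data.frame(f$lm))
  lse <- mx + log(rowSums(exp(f$lm - mx)))
  ltrue <- f$lm[cbind(seq_along(f$mv), f$mv + 1L)]
  mean(lse - ltrue)
}

#' Weighted Dice loss
#'
#' `1 - sum_c w_c * (2 * sum(p_c y_c) + s) / (sum p_c + sum y_c + s)` with
#' class weights `w_c` per the configuration (normalized to sum 1) and
#' smoothing `s`.
#'
#' @param probs softmax probabilities `(H, W, nc[, N])` (rows sum to 1).
#' @param mask integer labels `(H, W[, N])`.
#' @param cfg a [loss_config()].
#' @return scalar in `[0, 1]`.
#' @export
weighted_dice <- function(probs, mask, cfg = loss_config()) {
  f <- loss_flatten(probs, mask)
  w <- dice_class_weights(f$mv, f$nc, cfg$class_weighting)
  s <- cfg$dice_smooth
  loss <- 1
  for (c in seq_len(f$nc)) {
    yc <- as.numeric(f$mv == c - 1L)
    pc <- f$lm[, c]
    dc <- (2 * sum(pc * yc) + s) / (sum(pc) + sum(yc) + s)
    loss <- loss - w[c] * dc
  }
  loss
}

#' Combined segmentation loss
#'
#' `ce_weight * cross-entropy + dice_weight * weighted Dice`, both computed
#' from the same logits (Dice through the softmax).
#'
#' @inheritParams cross_entropy
#' @param cfg a [loss_config()].
#' @return scalar; the individual terms are attached as attributes `ce` and
#'   `dice`.
#' @export
combined_loss <- function(logits, mask, cfg = loss_config()) {
  ce <- cross_entropy(logits, mask)
  f <- loss_flatten(logits, mask)
  p <- softmax_rows(f$lm)
  d <- dim(logits)
  if (length(d) == 3L) d <- c(d, 1L)
  parr <- aperm(array(p, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  dc <- weighted_dice(parr, mask, cfg)
  structure(cfg$ce_weight * ce + cfg$dice_weight * dc, ce = ce, dice = dc)
}

# Fused differentiable loss op used by the training loop: value + analytic
# gradient with respect to the logits. Returns a scalar tape node with the
# term values attached to the node environment.
ag_seg_loss <- function(logits, mask, cfg = loss_config()) {
  lv <- ag_value(logits)
  d <- dim(lv)
  if (length(d) == 3L) d <- c(d, 1L)
  f <- loss_flatten(lv, mask)
  npix <- nrow(f$lm)
  nc <- f$nc
  p <- softmax_rows(f$lm)
  y <- matrix(0, npix, nc)
  y[cbind(seq_len(npix), f$mv + 1L)] <- 1
  ce <- -mean(log(pmax(p[cbind(seq_len(npix), f$mv + 1L)], 1e-300)))
  w <- dice_class_weights(f$mv, nc, cfg$class_weighting)
  s <- cfg$dice_smooth
  I <- colSums(p * y)
  U <- colSums(p) + colSums(y)
  dice <- 1 - sum(w * (2 * I + s) / (U + s))
  total <- cfg$ce_weight * ce + cfg$dice_weight * dice
  node <- ag_op(total, list(logits), function(g) {
    gce <- (p - y) / npix
    # d(dice-loss)/dp_cj = -w_c (2 y_cj (U_c+s) - (2 I_c+s)) / (U_c+s)^2
    num <- sweep(2 * y, 2, U + s, "*")
    gdice <- -sweep(sweep(num, 2, 2 * I + s), 2, (U + s)^2, "/")
    gdice <- sweep(gdice, 2, w, "*")
    # chain through softmax for the dice part only (gce is already d/dlogits)
    glog <- cfg$ce_weight * gce +
      cfg$dice_weight * p * (sweep(gdice, 1, rowSums(gdice * p)))
    glog <- glog * as.numeric(g)
    dlog <- aperm(array(glog, dim = c(d[1], d[2], d[4], nc)), c(1, 2, 4, 3))
    list(dlog)
  })
  if (is_node(node)) {
    node$ce <- ce
    node$dice <- dice
  }
  node
}
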