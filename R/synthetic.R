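# Synthetic curvilinear-fiber phantom generator emulating TEM micrographs of
# peptide nanowires (dark slender fibers on a brighter, blurred, noisy
# background), the threshold + morphology annotation pipeline, and the
# split/crop dataset protocol.

#' Synthetic image configuration
#'
#' Defaults emulate the source imagery: dark fibers (`wire_level` 50) on a
#' bright field (`background_level` 170) with a mild illumination gradient,
#' Gaussian blur and additive Gaussian noise. The `dispersed` regime renders
#' few fibers with only incidental overlap; `network` renders many entangled
#' fibers with frequent crossings.
#'
#' @param image_size `(H, W)` in pixels (default 512 x 512).
#' @param n_wires integer range (length-2) of fiber counts; defaults depend on
#'   the regime (3-8 dispersed, 15-30 network).
#' @param wire_width_px numeric range of stroke widths in pixels.
#' @param curvature standard deviation (radians) of the per-step heading
#'   increment of the random fiber path; larger = wigglier fibers.
#' @param regime `"dispersed"` or `"network"`.
#' @param background_level,wire_level 8-bit gray levels; the wire must be
#'   darker than the background.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param noise_sd additive Gaussian noise standard deviation (gray levels).
#' @param illumination_gradient peak-to-peak amplitude of a random linear
#'   illumination ramp (gray levels).
#' @param seed integer seed; a sample is a pure function of its config.
#' @return A `wbs_synth_config` list.
#' @export
synthetic_config <- function(image_size = c(512L, 512L),
                             n_wires = NULL,
                             wire_width_px = c(4, 8),
                             curvature = 0.15,
                             regime = c("dispersed", "network"),
                             background_level = 170,
                             wire_level = 50,
                             blur_sigma = 1.0,
                             noise_sd = 8,
                             illumination_gradient = 15,
                             seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(n_wires)) {
    n_wires <- if (regime == "dispersed") c(3L, 8L) else c(15L, 30L)
  }
  if (length(n_wires) == 1L) n_wires <- rep(n_wires, 2L)
  if (wire_level >= background_level) {
    stop("wire_level must be darker (smaller) than background_level",
         call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 n_wires = as.integer(n_wires),
                 wire_width_px = wire_width_px,
                 curvature = curvature, regime = regime,
                 background_level = background_level,
                 wire_level = wire_level, blur_sigma = blur_sigma,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "wbs_synth_config")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Separable Gaussian blur with edge replication.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in -r:r) {
    rows <- pmin(pmax(seq_len(H) + i, 1L), H)
    out <- out + k[i + r + 1L] * x[rows, , drop = FALSE]
  }
  out2 <- matrix(0, H, W)
  for (j in -r:r) {
    cols <- pmin(pmax(seq_len(W) + j, 1L), W)
    out2 <- out2 + k[j + r + 1L] * out[, cols, drop = FALSE]
  }
  out2
}

# Rasterize one smooth random-heading path of given stroke width into mask.
stamp_wire <- function(mask, H, W, width, curvature) {
  len <- round(stats::runif(1, 0.5, 1.2) * max(H, W))
  y <- stats::runif(1, 1, H)
  x <- stats::runif(1, 1, W)
  heading <- stats::runif(1, 0, 2 * pi) +
    cumsum(stats::rnorm(len, 0, curvature))
  ys <- y + cumsum(sin(heading))
  xs <- x + cumsum(cos(heading))
  pts <- unique(cbind(round(ys), round(xs)))
  rad <- width / 2
  ri <- ceiling(rad)
  for (dy in -ri:ri) {
    for (dx in -ri:ri) {
      if (dy^2 + dx^2 > rad^2) next
      py <- pts[, 1] + dy
      px <- pts[, 2] + dx
      ok <- py >= 1 & py <= H & px >= 1 & px <= W
      if (any(ok)) mask[cbind(py[ok], px[ok])] <- 1L
    }
  }
  mask
}

#' Generate one synthetic fiber image with its ground-truth mask
#'
#' Renders `n_wires` smooth random curvilinear paths (integrated random
#' headings, increments `~ Normal(0, curvature)`) at the configured stroke
#' width into a hard binary mask; the image is the background level plus a
#' random linear illumination ramp, with wire pixels set to the (darker) wire
#' level, Gaussian-blurred, corrupted with additive Gaussian noise, and
#' clipped to `[0, 255]`. Fully reproducible from the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return A `wbs_sample`: list with `image` (integer matrix, 0-255), `mask`
#'   (integer matrix, 0/1) and `meta` (seed, regime, n_wires).
#' @export
generate_sample <- function(cfg = synthetic_config()) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  if (max(cfg$wire_width_px) > min(H, W)) {
    stop("wire width exceeds image size", call. = FALSE)
  }
  with_seed(cfg$seed, {
    nw <- if (cfg$n_wires[1] == cfg$n_wires[2]) cfg$n_wires[1] else
      sample(cfg$n_wires[1]:cfg$n_wires[2], 1L)
    mask <- matrix(0L, H, W)
    if (nw > 0) {
      for (i in seq_len(nw)) {
        wd <- stats::runif(1, cfg$wire_width_px[1], cfg$wire_width_px[2])
        mask <- stamp_wire(mask, H, W, wd, cfg$curvature)
      }
    }
    theta <- stats::runif(1, 0, 2 * pi)
    gy <- matrix(seq_len(H) / H - 0.5, H, W)
    gx <- matrix(rep(seq_len(W) / W - 0.5, each = H), H, W)
    ramp <- cfg$illumination_gradient * (cos(theta) * gx + sin(theta) * gy)
    img <- matrix(cfg$background_level, H, W) + ramp
    img[mask == 1L] <- cfg$wire_level
    img <- gauss_blur(img, cfg$blur_sigma)
    img <- img + stats::rnorm(H * W, 0, cfg$noise_sd)
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), H, W)
    structure(list(image = img, mask = mask,
                   meta = list(seed = cfg$seed, regime = cfg$regime,
                               n_wires = nw)),
              class = "wbs_sample")
  })
}

# --- annotation pipeline -----------------------------------------------------

#' Annotation pipeline parameters
#'
#' Printed defaults of the threshold + morphology mask-derivation procedure:
#' 3x3 median filter, HSV dual thresholds `S < 40` and `V < 90` (0-255
#' scales), one opening, two closings, one pixel of final dilation, all with a
#' full 3x3 structuring element.
#'
#' @param median_kernel median filter size (only 3 supported).
#' @param s_max,v_max HSV thresholds on 0-255 scales.
#' @param opening_iters,closing_iters,dilation_px morphology iteration counts.
#' @return A `wbs_annotation_params` list.
#' @export
annotation_params <- function(median_kernel = 3L, s_max = 40, v_max = 90,
                              opening_iters = 1L, closing_iters = 2L,
                              dilation_px = 1L) {
  if (median_kernel != 3L) stop("only a 3x3 median filter is supported",
                                call. = FALSE)
  structure(list(median_kernel = 3L, s_max = s_max, v_max = v_max,
                 opening_iters = opening_iters,
                 closing_iters = closing_iters,
                 dilation_px = dilation_px),
            class = "wbs_annotation_params")
}

#' Binary erosion / dilation with a full 3x3 structuring element
#'
#' Out-of-image neighbours are ignored: erosion behaves as if padded with
#' foreground, dilation as if padded with background, so a uniform mask is a
#' fixed point of both.
#'
#' @param mask integer/logical matrix (0/1).
#' @return integer matrix (0/1).
#' @export
binary_erode <- function(mask) {
  m <- wbs_morph3(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)), TRUE)
  m
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask) {
  wbs_morph3(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)), FALSE)
}

#' @rdname binary_erode
#' @export
binary_opening <- function(mask) binary_dilate(binary_erode(mask))

#' @rdname binary_erode
#' @export
binary_closing <- function(mask) binary_erode(binary_dilate(mask))

# RGB (0-255) to HSV saturation/value on 0-255 scales (hue not needed).
rgb_to_sv <- function(img) {
  if (length(dim(img)) == 2L) {
    return(list(s = matrix(0, nrow(img), ncol(img)), v = img * 1.0))
  }
  v <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- ifelse(v == 0, 0, (v - mn) / v * 255)
  list(s = s, v = v)
}

#' Derive a binary mask from a micrograph by thresholding + morphology
#'
#' 3x3 median filter, conversion to HSV (a grayscale image is replicated to
#' three channels, making saturation identically zero so the value threshold
#' governs), initial mask `S < s_max & V < v_max`, then opening, closing and
#' dilation with a 3x3 structuring element per the parameters.
#'
#' @param image matrix (grayscale, 0-255) or `(H, W, 3)` RGB array.
#' @param params an [annotation_params()].
#' @return integer matrix (0/1).
#' @export
annotate_mask <- function(image, params = annotation_params()) {
  if (length(dim(image)) == 3L) {
    med <- image
    for (c in 1:3) med[, , c] <- wbs_median3(image[, , c] * 1.0)
  } else {
    med <- wbs_median3(image * 1.0)
  }
  sv <- rgb_to_sv(med)
  m <- matrix(as.integer(sv$s < params$s_max & sv$v < params$v_max),
              nrow(sv$v), ncol(sv$v))
  for (i in seq_len(params$opening_iters)) m <- binary_opening(m)
  for (i in seq_len(params$closing_iters)) m <- binary_closing(m)
  for (i in seq_len(params$dilation_px)) m <- binary_dilate(m)
  m
}

# --- dataset protocol --------------------------------------------------------

#' Split whole images into train/val/test and crop into patches
#'
#' The split is performed at the source-image level before cropping, so no
#' patch of one image can appear in two splits. Each image is cut into a
#' non-overlapping grid of `patch x patch` tiles; remainder margins are
#' discarded.
#'
#' @param samples list of `wbs_sample` objects.
#' @param ratio length-3 positive weights, default `c(7, 2, 1)`.
#' @param patch patch side in pixels.
#' @param seed integer seed for the image-level shuffle.
#' @return A `wbs_dataset`: list with `train`, `val`, `test` (lists of patch
#'   samples) and a `manifest` data frame (split, source image, patch origin).
#' @export
split_and_crop <- function(samples, ratio = c(7, 2, 1), patch, seed = 1L) {
  if (length(ratio) != 3L || any(ratio < 0) || sum(ratio) <= 0) {
    stop("ratio must be three nonnegative weights", call. = FALSE)
  }
  dims <- vapply(samples, function(s) dim(s$image), integer(2))
  if (patch > min(dims)) stop("patch exceeds the smallest image dimension",
                              call. = FALSE)
  n <- length(samples)
  idx <- with_seed(seed, sample.int(n))
  n_tr <- floor(n * ratio[1] / sum(ratio))
  n_va <- floor(n * ratio[2] / sum(ratio))
  split_of <- rep("test", n)
  split_of[idx[seq_len(n_tr)]] <- "train"
  if (n_va > 0) split_of[idx[n_tr + seq_len(n_va)]] <- "val"
  out <- list(train = list(), val = list(), test = list())
  man <- list()
  for (i in seq_len(n)) {
    s <- samples[[i]]
    H <- nrow(s$image); W <- ncol(s$image)
    for (py in seq_len(H %/% patch)) {
      for (px in seq_len(W %/% patch)) {
        rows <- (py - 1L) * patch + seq_len(patch)
        cols <- (px - 1L) * patch + seq_len(patch)
        ps <- structure(list(image = s$image[rows, cols],
                             mask = s$mask[rows, cols],
                             meta = c(s$meta, list(source = i,
                                                   y0 = rows[1], x0 = cols[1],
                                                   split = split_of[i]))),
                        class = "wbs_sample")
        out[[split_of[i]]] <- c(out[[split_of[i]]], list(ps))
        man[[length(man) + 1L]] <- data.frame(split = split_of[i], source = i,
                                              y0 = rows[1], x0 = cols[1])
      }
    }
  }
  out$manifest <- do.call(rbind, man)
  class(out) <- "wbs_dataset"
  out
}

#' Write / read a dataset as paired PNG files plus a JSON manifest
#'
#' Images are 8-bit grayscale PNGs; masks are 8-bit PNGs with background 0 and
#' foreground 255. `read_dataset()` validates that every manifest entry has
#' both files and that masks are strictly binary, and fails naming the
#' offending file otherwise. The round trip is bitwise exact.
#'
#' @param dataset a `wbs_dataset` from [split_and_crop()].
#' @param dir output directory (created if needed).
#' @return `write_dataset()`: the manifest (invisibly); `read_dataset()`: the
#'   reconstructed `wbs_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (split in c("train", "val", "test")) {
    dir.create(file.path(dir, split), showWarnings = FALSE)
    for (i in seq_along(dataset[[split]])) {
      s <- dataset[[split]][[i]]
      img_f <- file.path(split, sprintf("img_%04d.png", i))
      msk_f <- file.path(split, sprintf("mask_%04d.png", i))
      png::writePNG(s$image / 255, file.path(dir, img_f))
      png::writePNG(s$mask * 1.0, file.path(dir, msk_f))
      entries[[length(entries) + 1L]] <-
        c(list(split = split, image = img_f, mask = msk_f),
          s$meta[setdiff(names(s$meta), "split")])
    }
  }
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(entries)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest: ", mf, call. = FALSE)
  entries <- jsonlite::read_json(mf, simplifyVector = FALSE)
  out <- list(train = list(), val = list(), test = list())
  man <- list()
  for (e in entries) {
    img_p <- file.path(dir, e$image)
    msk_p <- file.path(dir, e$mask)
    for (p in c(img_p, msk_p)) {
      if (!file.exists(p)) stop("dataset integrity error: missing file ", p,
                                call. = FALSE)
    }
    img <- tryCatch(png::readPNG(img_p), error = function(err)
      stop("dataset integrity error: unreadable file ", img_p, call. = FALSE))
    msk <- tryCatch(png::readPNG(msk_p), error = function(err)
      stop("dataset integrity error: unreadable file ", msk_p, call. = FALSE))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    if (!all(msk %in% c(0, 1))) {
      stop("dataset integrity error: non-binary mask ", msk_p, call. = FALSE)
    }
    s <- structure(list(image = matrix(as.integer(round(img * 255)),
                                       nrow(img), ncol(img)),
                        mask = matrix(as.integer(msk), nrow(msk), ncol(msk)),
                        meta = e[setdiff(names(e), c("split", "image",
                                                     "mask"))]),
                   class = "wbs_sample")
    out[[e$split]] <- c(out[[e$split]], list(s))
    man[[length(man) + 1L]] <- data.frame(split = e$split,
                                          image = e$image, mask = e$mask)
  }
  out$manifest <- do.call(rbind, man)
  class(out) <- "wbs_dataset"
  out
}
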