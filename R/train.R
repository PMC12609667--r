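# Training loop (Adam + plateau scheduler), evaluation, checkpointing,
# ablation driver and bootstrap model comparison.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 0.01 and
#' momentum parameters (0.99, 0.99), L2 weight decay 0.001, batch size 16,
#' 300 epochs, He initialization, inputs normalized to `[0, 1]`, and a
#' reduce-on-plateau schedule that halves the learning rate when validation
#' mIoU stalls.
#'
#' @param lr initial learning rate.
#' @param betas Adam `(beta1, beta2)`.
#' @param weight_decay L2 penalty coefficient (added to the gradient).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param plateau_factor multiplicative learning-rate reduction.
#' @param plateau_patience epochs without validation-mIoU improvement before a
#'   reduction.
#' @param seed integer seed controlling initialization and batch order.
#' @param loss a [loss_config()].
#' @param network a [network_config()].
#' @param n_runs number of independent seeds for repeated runs (ablation).
#' @return A `wbs_train_config` list.
#' @export
train_config <- function(lr = 0.01, betas = c(0.99, 0.99),
                         weight_decay = 0.001, batch_size = 16L,
                         epochs = 300L, plateau_factor = 0.5,
                         plateau_patience = 10L, seed = 1L,
                         loss = loss_config(), network = network_config(),
                         n_runs = 5L) {
  stopifnot(lr > 0, plateau_factor > 0, plateau_factor < 1, batch_size >= 1)
  structure(list(lr = lr, betas = betas, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed), loss = loss, network = network,
                 n_runs = as.integer(n_runs)),
            class = "wbs_train_config")
}

# Stack samples into a (H, W, 3, N) input ([0,1], gray replicated) and a
# (H, W, N) label array.
samples_to_batch <- function(samples, idx = seq_along(samples)) {
  H <- nrow(samples[[idx[1]]]$image)
  W <- ncol(samples[[idx[1]]]$image)
  N <- length(idx)
  x <- array(0, dim = c(H, W, 3L, N))
  y <- array(0L, dim = c(H, W, N))
  for (i in seq_len(N)) {
    g <- samples[[idx[i]]]$image / 255
    x[, , 1, i] <- g; x[, , 2, i] <- g; x[, , 3, i] <- g
    y[, , i] <- samples[[idx[i]]]$mask
  }
  list(x = x, y = y)
}

# --- Adam ---------------------------------------------------------------------

adam_new <- function(params, betas, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st$betas <- betas
  st$eps <- eps
  st
}

adam_step <- function(st, params, lr, weight_decay = 0) {
  st$t <- st$t + 1L
  b1 <- st$betas[1]; b2 <- st$betas[2]
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    p$value <- p$value - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  invisible(st)
}

# --- batch-norm recalibration ---------------------------------------------
# At desk scale the weights move quickly relative to the momentum-0.1
# exponential running averages, so inference statistics lag the trained
# network badly. Following the original batch-normalization prescription, the
# population statistics are re-estimated after weight updates by averaging
# batch statistics over a few training minibatches (cumulative average via
# momentum 1/k), which the exponential average merely approximates.

walk_bn <- function(m, f) {
  if (length(m$buffers)) f(m)
  for (ch in m$children) walk_bn(ch, f)
  invisible(NULL)
}

bn_recalibrate <- function(net, samples, batch_size = 16L, max_batches = 4L) {
  starts <- seq(1L, length(samples), by = batch_size)
  starts <- starts[seq_len(min(length(starts), max_batches))]
  k <- 0L
  for (s in starts) {
    k <- k + 1L
    walk_bn(net, function(m) m$momentum <- 1 / k)
    idx <- s:min(s + batch_size - 1L, length(samples))
    b <- samples_to_batch(samples, idx)
    with_no_grad(network_forward(net, b$x, training = TRUE))
  }
  walk_bn(net, function(m) m$momentum <- 0.1)
  invisible(net)
}

# --- training -----------------------------------------------------------------

#' Train a segmentation network
#'
#' Full loop: He-initialized network, Adam with the configured learning rate
#' and betas, L2 weight decay folded into the gradient, per-epoch validation
#' mIoU, reduce-on-plateau learning-rate halving, and retention of the
#' best-validation-mIoU weights. Deterministic given the config seed.
#'
#' @param cfg a [train_config()].
#' @param train_set,val_set lists of `wbs_sample` objects.
#' @param verbose print a per-epoch summary line.
#' @return list with `net` (final weights), `best_state` (state dict of the
#'   best validation epoch), `best_miou`, `history` (one row per epoch:
#'   epoch, loss, ce, dice, val_miou, lr) and `config`.
#' @export
train <- function(cfg, train_set, val_set, verbose = FALSE) {
  stopifnot(inherits(cfg, "wbs_train_config"))
  if (length(train_set) == 0) stop("empty training set", call. = FALSE)
  with_seed(cfg$seed, {
    net <- build_network(cfg$network)
    params <- nn_parameters(net)
    opt <- adam_new(params, cfg$betas)
    lr <- cfg$lr
    best_miou <- -Inf
    best_state <- nn_state_dict(net)
    bad_epochs <- 0L
    hist <- vector("list", cfg$epochs)
    n <- length(train_set)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- ep_ce <- ep_dice <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        b <- samples_to_batch(train_set, idx)
        logits <- network_forward(net, b$x, training = TRUE)
        loss <- ag_seg_loss(logits, b$y, cfg$loss)
        if (!is.finite(loss$value)) {
          stop(sprintf(paste0("non-finite loss at epoch %d (lr %.2e, batch ",
                              "mean %.3f, sd %.3f)"),
                       epoch, lr, mean(b$x), stats::sd(b$x)), call. = FALSE)
        }
        ag_zero_grad(params)
        ag_backward(loss)
        adam_step(opt, params, lr, cfg$weight_decay)
        w <- length(idx) / n
        ep_loss <- ep_loss + loss$value * w
        ep_ce <- ep_ce + loss$ce * w
        ep_dice <- ep_dice + loss$dice * w
      }
      bn_recalibrate(net, train_set, cfg$batch_size)
      val_miou <- NA_real_
      if (length(val_set) > 0) {
        ev <- evaluate(net, val_set, quiet = TRUE)
        val_miou <- ev$report$miou
        if (val_miou > best_miou + 1e-8) {
          best_miou <- val_miou
          best_state <- nn_state_dict(net)
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
          if (bad_epochs > cfg$plateau_patience) {
            lr <- lr * cfg$plateau_factor
            bad_epochs <- 0L
          }
        }
      }
      hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss, ce = ep_ce,
                                  dice = ep_dice, val_miou = val_miou,
                                  lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  (ce %.4f dice %.4f)  val mIoU %s  lr %.2e",
                        epoch, ep_loss, ep_ce, ep_dice,
                        ifelse(is.na(val_miou), "-", sprintf("%.4f", val_miou)),
                        lr))
      }
    }
    history <- if (cfg$epochs > 0) do.call(rbind, hist) else
      data.frame(epoch = integer(), loss = numeric(), ce = numeric(),
                 dice = numeric(), val_miou = numeric(), lr = numeric())
    if (!is.finite(best_miou)) best_state <- nn_state_dict(net)
    list(net = net, best_state = best_state,
         best_miou = if (is.finite(best_miou)) best_miou else NA_real_,
         history = history, config = cfg)
  })
}

#' Evaluate a network on a test set
#'
#' Accumulates one global confusion matrix over all pixels (micro average) and
#' keeps the per-image mIoU list needed for bootstrap comparison.
#'
#' @param net a trained network (or the result of [load_checkpoint()]).
#' @param test_set list of `wbs_sample` objects.
#' @param batch_size evaluation minibatch size.
#' @param quiet suppress per-image zero-union warnings.
#' @return list with `report` ([metrics_report()] of the global matrix),
#'   `per_image_miou`, `per_image_fg_iou` and the global `confusion` matrix.
#' @export
evaluate <- function(net, test_set, batch_size = 8L, quiet = FALSE) {
  if (length(test_set) == 0) stop("empty test set", call. = FALSE)
  nc <- net$config$num_classes
  cm <- confusion_matrix(nc)
  pm <- numeric(length(test_set))
  pf <- numeric(length(test_set))
  starts <- seq(1L, length(test_set), by = batch_size)
  k <- 0L
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(test_set))
    b <- samples_to_batch(test_set, idx)
    pred <- with_no_grad(
      logits_to_mask(network_forward(net, b$x, training = FALSE)))
    for (i in seq_along(idx)) {
      k <- k + 1L
      cmi <- cm_accumulate(pred[, , i], b$y[, , i], confusion_matrix(nc))
      cm <- cm + cmi
      pm[k] <- if (quiet) suppressWarnings(miou(cmi)) else miou(cmi)
      iou <- per_class_iou(cmi)
      pf[k] <- if (length(iou) >= 2) iou[2] else NA_real_
    }
  }
  list(report = metrics_report(cm), per_image_miou = pm,
       per_image_fg_iou = pf, confusion = cm)
}

# --- checkpointing ------------------------------------------------------------

#' Save / load a network checkpoint
#'
#' A checkpoint is a single serialized archive holding the format version, the
#' network configuration and the full state dict (weights + batch-norm
#' running statistics), so `load_checkpoint()` rebuilds an identical network.
#'
#' @param net a network from [build_network()] (possibly trained).
#' @param path file path.
#' @param state optional state dict to save instead of the network's current
#'   one (e.g. `best_state` from [train()]).
#' @return `save_checkpoint()`: the path, invisibly. `load_checkpoint()`: the
#'   reconstructed network.
#' @export
save_checkpoint <- function(net, path, state = NULL) {
  obj <- list(format = "wavebisenet-checkpoint-1",
              config = net$config,
              state = if (is.null(state)) nn_state_dict(net) else state)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "wavebisenet-checkpoint-1")) {
    stop("not a recognized checkpoint file: ", path, call. = FALSE)
  }
  net <- build_network(obj$config)
  nn_load_state_dict(net, obj$state)
  net
}

# --- ablation / comparison ----------------------------------------------------

#' Run the ablation grid
#'
#' Trains each variant `n_runs` times with consecutive seeds and reports
#' mean and standard deviation of mIoU, accuracy, F1 and kappa on the test
#' set. With `n_runs = 1` the standard deviation is reported as 0 and flagged
#' in the `sd_degenerate` column.
#'
#' @param base_cfg a [train_config()]; its network config supplies everything
#'   but the variant.
#' @param variants character vector of network variants.
#' @param n_runs runs per variant (defaults to `base_cfg$n_runs`).
#' @param train_set,val_set,test_set sample lists.
#' @param csv_path optional path; the per-run table is written as CSV.
#' @return list with `runs` (one row per run) and `summary`
#'   (mean +/- sd per variant).
#' @export
run_ablation <- function(base_cfg, variants, train_set, val_set, test_set,
                         n_runs = NULL, csv_path = NULL) {
  allowed <- c("wavebisenet", "bisenetv1", "bisenetv1+dwcm", "bisenetv1+fum")
  if (!all(variants %in% allowed)) {
    stop("variants must be a subset of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(n_runs)) n_runs <- base_cfg$n_runs
  rows <- list()
  for (v in variants) {
    for (run in seq_len(n_runs)) {
      cfg <- base_cfg
      cfg$seed <- base_cfg$seed + run - 1L
      cfg$network$variant <- v
      fit <- train(cfg, train_set, val_set)
      net <- build_network_from_state(cfg$network, fit$best_state)
      ev <- evaluate(net, test_set, quiet = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, run = run, seed = cfg$seed,
        miou = ev$report$miou, accuracy = ev$report$accuracy,
        f1 = ev$report$f1, kappa = ev$report$kappa)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(
    runs[c("miou", "accuracy", "f1", "kappa")], by = list(variant = runs$variant), FUN = f)
  mu <- agg(mean)
  sdv <- agg(function(z) if (length(z) > 1) stats::sd(z) else 0)
  names(sdv)[-1] <- paste0(names(sdv)[-1], "_sd")
  summary <- merge(mu, sdv, by = "variant")
  summary$sd_degenerate <- n_runs == 1L
  if (!is.null(csv_path)) utils::write.csv(runs, csv_path, row.names = FALSE)
  list(runs = runs, summary = summary)
}

build_network_from_state <- function(net_cfg, state) {
  net <- with_seed(0L, build_network(net_cfg))
  nn_load_state_dict(net, state)
  net
}

#' Compare two models' per-image scores by paired bootstrap
#'
#' Delegates to [bootstrap_compare()] (10,000 resamples by default) and
#' optionally writes a histogram of the resampled score difference with the
#' confidence interval marked.
#'
#' @param scores_a,scores_b paired per-image scores.
#' @param n_resamples bootstrap resamples.
#' @param seed RNG seed.
#' @param plot_file optional PNG path for the difference histogram.
#' @return a `wbs_bootstrap` object.
#' @export
compare_models <- function(scores_a, scores_b, n_resamples = 10000L,
                           seed = 1L, plot_file = NULL) {
  bs <- bootstrap_compare(scores_a, scores_b, n_resamples, seed)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    graphics::hist(bs$diffs, breaks = 50, col = "lightblue",
                   main = "Bootstrap difference distribution",
                   xlab = "score difference (B - A)")
    graphics::abline(v = 0, lwd = 2)
    graphics::abline(v = bs$diff_ci, lty = 2, col = "darkorange", lwd = 2)
  }
  bs
}

#' Desk-scale training benchmark
#'
#' The package's reference micro-study: 200 synthetic 64 x 64 dispersed-fiber
#' images (split 7:2:1 at the image level), a width-reduced network
#' (`width_mult = 0.25`), 30 epochs on CPU with the standard recipe. Returns
#' the training history and held-out metrics, including foreground IoU.
#'
#' @param seed integer seed (controls data and training).
#' @param n_images,epochs,width_mult study-size knobs (defaults are the
#'   reference conditions).
#' @param variant network variant to train.
#' @param verbose print per-epoch progress.
#' @return list with `history`, `report`, `fg_iou` (held-out foreground IoU),
#'   `per_image_miou` and the trained `net`.
#' @export
micro_benchmark <- function(seed = 1L, n_images = 200L, epochs = 30L,
                            width_mult = 0.25, variant = "wavebisenet",
                            verbose = FALSE) {
  samples <- lapply(seq_len(n_images), function(i) {
    generate_sample(synthetic_config(
      image_size = c(64L, 64L), n_wires = c(2L, 4L),
      wire_width_px = c(3, 5), curvature = 0.2, blur_sigma = 0.8,
      noise_sd = 5, illumination_gradient = 10,
      seed = seed * 10000L + i))
  })
  ds <- split_and_crop(samples, ratio = c(7, 2, 1), patch = 64L, seed = seed)
  cfg <- train_config(
    epochs = epochs, seed = seed,
    network = network_config(input_size = c(64L, 64L), width_mult = width_mult,
                             variant = variant))
  fit <- train(cfg, ds$train, ds$val, verbose = verbose)
  net <- build_network_from_state(cfg$network, fit$best_state)
  ev <- evaluate(net, ds$test, quiet = TRUE)
  list(history = fit$history, report = ev$report,
       fg_iou = ev$report$per_class_iou[2],
       per_image_miou = ev$per_image_miou, net = net)
}
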