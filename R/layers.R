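# Trainable layer infrastructure. A module is an environment holding named
# parameter nodes, named child modules, optional buffers (e.g. batch-norm
# running statistics), and a forward(x, training) closure.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  m$buffers <- character(0)
  class(m) <- "wbs_module"
  m
}

#' @export
print.wbs_module <- function(x, ...) {
  np <- length(nn_parameters(x))
  nv <- sum(vapply(nn_parameters(x), function(p) length(p$value), numeric(1)))
  cat(sprintf("<wbs_module %s: %d parameter tensors, %d values>\n",
              x$type, np, nv))
  invisible(x)
}

# Flat named list of every parameter node in a module tree.
nn_parameters <- function(m) {
  out <- list()
  if (length(m$params)) {
    names_p <- names(m$params)
    for (i in seq_along(m$params)) {
      if (!is.null(m$params[[i]])) out[[names_p[i]]] <- m$params[[i]]
    }
  }
  for (nm in names(m$children)) {
    sub <- nn_parameters(m$children[[nm]])
    if (length(sub)) {
      names(sub) <- paste(nm, names(sub), sep = ".")
      out <- c(out, sub)
    }
  }
  out
}

# Named list of parameter values and buffers, for checkpointing.
nn_state_dict <- function(m) {
  out <- list()
  for (nm in names(m$params)) {
    if (!is.null(m$params[[nm]])) out[[nm]] <- m$params[[nm]]$value
  }
  for (bn in m$buffers) out[[bn]] <- m[[bn]]
  for (nm in names(m$children)) {
    sub <- nn_state_dict(m$children[[nm]])
    if (length(sub)) {
      names(sub) <- paste(nm, names(sub), sep = ".")
      out <- c(out, sub)
    }
  }
  out
}

nn_load_state_dict <- function(m, sd) {
  for (nm in names(m$params)) {
    if (is.null(m$params[[nm]])) next
    stopifnot(nm %in% names(sd))
    stopifnot(length(sd[[nm]]) == length(m$params[[nm]]$value))
    v <- sd[[nm]]
    if (!is.null(dim(m$params[[nm]]$value))) dim(v) <- dim(m$params[[nm]]$value)
    m$params[[nm]]$value <- v
  }
  for (bn in m$buffers) m[[bn]] <- sd[[bn]]
  for (nm in names(m$children)) {
    pref <- paste0(nm, ".")
    keep <- startsWith(names(sd), pref)
    sub <- sd[keep]
    names(sub) <- substring(names(sub), nchar(pref) + 1)
    nn_load_state_dict(m$children[[nm]], sub)
  }
  invisible(m)
}

mod_forward <- function(m, x, training = FALSE) m$forward(x, training)

# --- primitive layers -------------------------------------------------------

# 2-d convolution, He-initialized (fan-in), zero bias.
nn_conv2d <- function(cin, cout, k = 1L, stride = 1L, pad = 0L, bias = TRUE,
                      init = c("he", "zero", "identity")) {
  init <- match.arg(init)
  m <- new_module(sprintf("conv2d(%dx%d %d->%d)", k, k, cin, cout))
  w <- switch(init,
    he = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               dim = c(k, k, cin, cout)),
    zero = array(0, dim = c(k, k, cin, cout)),
    identity = conv_identity_weight(k, cin, cout))
  m$params$weight <- ag_param(w)
  m$params$bias <- if (bias) ag_param(rep(0, cout)) else NULL
  m$stride <- as.integer(stride)
  m$pad <- as.integer(pad)
  m$forward <- function(x, training = FALSE) {
    ag_conv2d(x, m$params$weight, m$params$bias, m$stride, m$pad)
  }
  m
}

# Identity-mapping weight for a k x k conv (center tap, channel i -> i mod cin).
conv_identity_weight <- function(k, cin, cout) {
  w <- array(0, dim = c(k, k, cin, cout))
  ctr <- (k + 1) %/% 2
  for (co in seq_len(cout)) w[ctr, ctr, ((co - 1) %% cin) + 1, co] <- 1
  w
}

nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new_module(sprintf("batchnorm(%d)", C))
  m$params$gamma <- ag_param(rep(1, C))
  m$params$beta <- ag_param(rep(0, C))
  m$running_mean <- rep(0, C)
  m$running_var <- rep(1, C)
  m$buffers <- c("running_mean", "running_var")
  m$momentum <- momentum
  m$eps <- eps
  m$forward <- function(x, training = FALSE) {
    ag_batchnorm(x, m$params$gamma, m$params$beta, m, training,
                 m$momentum, m$eps)
  }
  m
}

# conv -> BN -> ReLU, the standard fused stage (conv bias omitted, BN has one).
nn_conv_bn_relu <- function(cin, cout, k = 1L, stride = 1L, pad = 0L) {
  m <- new_module(sprintf("conv_bn_relu(%dx%d %d->%d)", k, k, cin, cout))
  m$children$conv <- nn_conv2d(cin, cout, k, stride, pad, bias = FALSE)
  m$children$bn <- nn_batchnorm(cout)
  m$forward <- function(x, training = FALSE) {
    ag_relu(mod_forward(m$children$bn,
                        mod_forward(m$children$conv, x, training), training))
  }
  m
}

nn_sequential <- function(...) {
  mods <- list(...)
  m <- new_module("sequential")
  names(mods) <- sprintf("m%d", seq_along(mods))
  m$children <- mods
  m$forward <- function(x, training = FALSE) {
    for (ch in m$children) x <- mod_forward(ch, x, training)
    x
  }
  m
}
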