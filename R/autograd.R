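# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A node is an environment holding a value, its parent nodes, and a
# vector-Jacobian-product closure that maps the incoming gradient to one
# gradient per parent. Parameters are leaf nodes that accumulate into $grad.
# When gradients are globally disabled (eval / inference), every op returns a
# plain array and no tape is built.

.ag <- new.env(parent = emptyenv())
.ag$enabled <- TRUE
.ag$next_id <- 0

ag_enabled <- function() isTRUE(.ag$enabled)

#' Evaluate an expression with gradient recording disabled
#'
#' Inside `expr`, all tape operations return plain arrays: no graph is built
#' and no backward pass is possible. Used for validation / inference passes.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_no_grad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- FALSE
  on.exit(.ag$enabled <- old)
  expr
}

is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, parents = list(), vjp = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$param <- param
  e$grad <- NULL
  .ag$next_id <- .ag$next_id + 1
  e$id <- as.character(.ag$next_id)
  class(e) <- "ag_node"
  e
}

#' Create a trainable parameter node
#' @param value numeric array initial value.
#' @keywords internal
ag_param <- function(value) new_node(value, param = TRUE)

# Record an op. `parents` may mix nodes and plain arrays; vjp(grad) must
# return a list aligned with `parents` (entries for plain arrays are ignored,
# and may be NULL).
ag_op <- function(value, parents, vjp) {
  if (!ag_enabled()) return(value)
  if (!any(vapply(parents, is_node, logical(1)))) return(value)
  new_node(value, parents = parents, vjp = vjp)
}

# Backward pass: reverse-topological sweep from `node`, seeding with `seed`
# (defaults to 1 for scalar losses). Gradients accumulate in $grad of every
# node on the tape; afterwards parameter nodes carry their gradients.
ag_backward <- function(node, seed = NULL) {
  stopifnot(is_node(node))
  if (is.null(seed)) {
    seed <- if (is.null(dim(node$value))) rep(1, length(node$value))
            else array(1, dim = dim(node$value))
  }
  order <- ag_topo(node)
  for (n in order) n$grad <- NULL
  node$grad <- seed
  for (n in order) {
    if (is.null(n$vjp) || is.null(n$grad)) next
    gs <- n$vjp(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!is_node(p) || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
    if (!n$param) n$grad <- NULL  # free intermediate gradients
  }
  invisible(node)
}

# Iterative DFS topological order (node first, ancestors later).
ag_topo <- function(root) {
  visited <- new.env(parent = emptyenv())
  order <- list()
  stack <- list(list(node = root, idx = 0L))
  addr <- function(n) n$id
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    n <- top$node
    key <- addr(n)
    if (is.null(visited[[key]])) visited[[key]] <- "open"
    kids <- Filter(is_node, n$parents)
    if (top$idx < length(kids)) {
      stack[[length(stack)]]$idx <- top$idx + 1L
      child <- kids[[top$idx + 1L]]
      ck <- addr(child)
      if (is.null(visited[[ck]])) {
        stack[[length(stack) + 1L]] <- list(node = child, idx = 0L)
      }
    } else {
      visited[[key]] <- "done"
      order[[length(order) + 1L]] <- n
      stack[[length(stack)]] <- NULL
    }
  }
  rev(order)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
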