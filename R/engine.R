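# Minimal reverse-mode autodiff engine for rank-4 feature maps.
#
# Values are plain R arrays with dim (B, C, H, W). A "node" is an environment
# holding $v (value) and, once backward has touched it, $g (gradient). Every
# differentiable op appends a backward closure to the context tape; gradients
# are accumulated by replaying the tape in reverse.

# ---- nodes ------------------------------------------------------------------

tnode <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e
}

is_tnode <- function(x) is.environment(x) && !is.null(x$v)

accum_grad <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Parameter: like a node but persistent, with momentum buffer for SGD.
param_tensor <- function(v, trainable = TRUE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$mom <- NULL
  e$trainable <- trainable
  e$name <- name
  class(e) <- "ew_param"
  e
}

# ---- context ----------------------------------------------------------------

#' Create a forward-pass context
#'
#' The context carries the autodiff tape, the train/eval switch for
#' normalisation layers, and a running FLOP counter (2 x multiply-accumulates
#' for dense ops, one operation per element for elementwise ops).
#'
#' @param grad record a tape for backpropagation?
#' @param training batch-statistics mode for batch normalisation?
#' @return an environment of class `ew_ctx`
#' @export
new_ctx <- function(grad = FALSE, training = FALSE) {
  e <- new.env(parent = emptyenv())
  e$grad <- grad
  e$training <- training
  e$tape <- vector("list", 256L)
  e$n <- 0L
  e$flops <- 0
  class(e) <- "ew_ctx"
  e
}

ctx_push <- function(ctx, fn) {
  n <- ctx$n + 1L
  if (n > length(ctx$tape)) ctx$tape <- c(ctx$tape, vector("list", length(ctx$tape)))
  ctx$tape[[n]] <- fn
  ctx$n <- n
  invisible(NULL)
}

add_flops <- function(ctx, x) {
  ctx$flops <- ctx$flops + x
  invisible(NULL)
}

# Run the tape backwards from a scalar loss node.
backward <- function(ctx, loss) {
  stopifnot(ctx$grad)
  loss$g <- 1
  if (ctx$n > 0L) for (i in rev(seq_len(ctx$n))) ctx$tape[[i]]()
  invisible(NULL)
}

# ---- modules ----------------------------------------------------------------

# A module is an environment with $pars (named list of ew_param), $sub (named
# list of child modules), $fwd(self, x, ctx), plus arbitrary config fields.
new_module <- function(type, fwd = NULL) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$pars <- list()
  m$sub <- list()
  m$fwd <- fwd
  class(m) <- c(paste0("ew_", type), "ew_module")
  m
}

#' Apply a module to a feature map
#'
#' @param module a module object created by one of the block constructors
#' @param x a feature map: numeric array with dim `(B, C, H, W)`, or a node
#' @param ctx optional context from [new_ctx()]; defaults to an inference
#'   context (no tape, running statistics for batch norm)
#' @return the output; an array if `x` was an array, otherwise a node
#' @export
forward <- function(module, x, ctx = NULL) {
  stopifnot(inherits(module, "ew_module"))
  plain <- FALSE
  wrap <- function(v) {
    if (is_tnode(v)) v else {
      check_feature_map(v)
      plain <<- TRUE
      tnode(v)
    }
  }
  xw <- if (is.list(x)) lapply(x, wrap) else wrap(x)
  if (is.null(ctx)) ctx <- new_ctx(grad = FALSE, training = FALSE)
  out <- module$fwd(module, xw, ctx)
  unwrap <- function(o) if (is_tnode(o)) o$v else if (is.list(o)) lapply(o, unwrap) else o
  if (plain) unwrap(out) else out
}

# Depth-first walk over all parameters of a module tree.
walk_params <- function(module, fn) {
  for (p in module$pars) fn(p)
  for (s in module$sub) walk_params(s, fn)
  invisible(NULL)
}

collect_params <- function(module) {
  out <- list()
  walk_params(module, function(p) out[[length(out) + 1L]] <<- p)
  out
}

#' Count parameters of a module or model
#'
#' Trainable parameter elements are reported in millions; frozen parameters
#' (e.g. the fixed Haar filter bank) are reported separately.
#'
#' @param module a module or assembled detection model
#' @return list with `params_millions`, `n_trainable`, `n_frozen`
#' @export
count_params <- function(module) {
  n_tr <- 0; n_fr <- 0
  walk_params(module, function(p) {
    if (isTRUE(p$trainable)) n_tr <<- n_tr + length(p$v) else n_fr <<- n_fr + length(p$v)
  })
  list(params_millions = n_tr / 1e6, n_trainable = n_tr, n_frozen = n_fr)
}

# Zero all gradients.
zero_grads <- function(module) {
  walk_params(module, function(p) p$g <- NULL)
  invisible(NULL)
}

# One SGD-with-momentum step over all trainable parameters.
sgd_step <- function(module, lr, momentum = 0.937, clip = 10) {
  # global gradient-norm clipping guards the smoke loop against rare spikes
  sq <- 0
  walk_params(module, function(p) {
    if (isTRUE(p$trainable) && !is.null(p$g)) sq <<- sq + sum(p$g^2)
  })
  gn <- sqrt(sq)
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  if (!is.finite(gn)) stop("non-finite gradient norm: training diverged")
  walk_params(module, function(p) {
    if (!isTRUE(p$trainable) || is.null(p$g)) return(invisible(NULL))
    g <- p$g * scale
    if (is.null(p$mom)) p$mom <- g else p$mom <- momentum * p$mom + g
    p$v <- p$v - lr * p$mom
    invisible(NULL)
  })
  invisible(gn)
}

# ---- feature-map contract ---------------------------------------------------

#' Validate a feature map
#'
#' A feature map is a rank-4 numeric array laid out `(batch, channels,
#' height, width)` with all entries finite.
#'
#' @param x candidate array
#' @return `x`, invisibly; errors if the contract is violated
#' @export
check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("feature map must be a rank-4 array (B, C, H, W)")
  if (any(dim(x) < 1L)) stop("feature map dims must all be >= 1")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

fm_shape <- function(x) {
  v <- if (is_tnode(x)) x$v else x
  d <- dim(v)
  list(B = d[1L], C = d[2L], H = d[3L], W = d[4L])
}

# Random helpers used across constructors (He-style uniform fan-in init).
init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  v <- stats::runif(prod(dims), -b, b)
  if (length(dims) == 1L) v else array(v, dim = dims)
}

# Evaluate fn with a temporary RNG seed, restoring RNG state afterwards.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
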