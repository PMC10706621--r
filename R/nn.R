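# Layer constructors, parameter handling, Adam and learning-rate schedules.
#
# A layer is a plain list holding its parameter nodes plus an `fwd` closure;
# a model is a nested list of layers. `collect_params()` walks the nesting
# and returns every trainable node, which is what the optimizer and the
# checkpoint writer operate on.

he_init <- function(fan_in, n, gain = 2) {
  stats::rnorm(n, sd = sqrt(gain / fan_in))
}

#' @keywords internal
layer_dense <- function(d_in, d_out, bias = TRUE, gain = 2) {
  W <- ag_param(matrix(he_init(d_in, d_in * d_out, gain), d_in, d_out))
  b <- if (bias) ag_param(numeric(d_out)) else NULL
  list(W = W, b = b,
       fwd = function(x) ag_dense(x, W, b))
}

#' @keywords internal
layer_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                         bias = TRUE, gain = 2) {
  w <- ag_param(array(he_init(k * k * cin, k * k * cin * cout, gain),
                      dim = c(k, k, cin, cout)))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  list(w = w, b = b, stride = stride, pad = pad,
       fwd = function(x) ag_conv2d(x, w, b, stride = stride, pad = pad))
}

# Per-channel affine normalization layer (fixed inference statistics:
# unit scale, zero shift at initialization) for (H, W, C) maps.
#' @keywords internal
layer_channel_norm <- function(c) {
  s <- ag_param(rep(1, c))
  t <- ag_param(numeric(c))
  list(s = s, t = t, fwd = function(x) ag_channel_affine(x, s, t))
}

# Affine normalization for length-c vectors.
#' @keywords internal
layer_vec_norm <- function(c) {
  s <- ag_param(rep(1, c))
  t <- ag_param(numeric(c))
  list(s = s, t = t, fwd = function(x) ag_vec_affine(x, s, t))
}

#' @keywords internal
layer_layernorm <- function(d) {
  g <- ag_param(rep(1, d))
  b <- ag_param(numeric(d))
  list(g = g, b = b, fwd = function(x) ag_layernorm(x, g, b))
}

#' Collect every trainable parameter node in a nested model list
#' @keywords internal
collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is_ag(v)) {
      if (isTRUE(v$req)) out[[length(out) + 1L]] <<- v
    } else if (is.list(v) && !is.function(v)) {
      for (el in v) walk(el)
    }
  }
  walk(x)
  out
}

#' Flatten parameter values to a single numeric vector (checkpointing)
#' @keywords internal
params_flatten <- function(params) {
  unlist(lapply(params, function(p) as.vector(p$value)), use.names = FALSE)
}

#' Write a flat numeric vector back into parameter nodes
#' @keywords internal
params_unflatten <- function(params, flat) {
  pos <- 0L
  for (p in params) {
    n <- length(p$value)
    vals <- flat[pos + seq_len(n)]
    dim(vals) <- dim(p$value)
    p$value <- vals
    pos <- pos + n
  }
  if (pos != length(flat)) stop("parameter vector length mismatch")
  invisible(params)
}

# ---- optimizer -------------------------------------------------------------

#' Adam optimizer state for a list of parameter nodes
#' @keywords internal
adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  # zero clones keep each parameter's exact shape (vector vs array)
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' One Adam update; parameters without gradients are skipped
#' @keywords internal
adam_step <- function(state, params, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (length(g) != length(p$value)) stop("adam_step: gradient shape mismatch")
    dim(g) <- dim(p$value)
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + state$eps)
  }
  state
}

# ---- learning-rate schedules ----------------------------------------------

#' Cosine-annealed learning rate
#'
#' Decays from `lr0` to `lr_min` over `total` steps following half a cosine
#' period, the schedule used for the depth-stage optimizer.
#' @param step current step (1-based)
#' @param total total number of steps
#' @param lr0 initial learning rate
#' @param lr_min final learning rate
#' @return learning rate for `step`
#' @export
lr_cosine <- function(step, total, lr0, lr_min = lr0 / 10) {
  frac <- min(max((step - 1) / max(total - 1, 1), 0), 1)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * frac))
}

#' Exponentially decayed learning rate
#'
#' `lr0 * decay^epoch`, the schedule used for the fusion-stage optimizer
#' (default decay rate 0.98 per epoch).
#' @param epoch 0-based epoch index
#' @param lr0 initial learning rate
#' @param decay multiplicative decay per epoch
#' @return learning rate for `epoch`
#' @export
lr_exponential <- function(epoch, lr0, decay = 0.98) {
  lr0 * decay^epoch
}
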