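# Reverse-mode automatic differentiation on dense R arrays.
#
# A computation is a DAG of nodes (environments). Leaf parameter nodes carry
# `requires_grad = TRUE`; every operation records its parents and a grad_fn
# that maps the incoming gradient to one gradient per parent (NULL for
# parents that do not require gradients). `ag_backward()` runs a topological
# sweep from a scalar loss node and accumulates gradients into `$grad`.
#
# The engine supports exactly the operations the nutrition models need:
# dense and 2-D convolutional layers, layer/channel normalization, the usual
# activations, softmax attention, pooling, broadcast gating and the
# geometric multi-task loss. Shapes follow the (H, W, C) convention for
# feature maps and (tokens, dim) for token matrices.

new_ag_node <- function(value, parents = list(), grad_fn = NULL) {
  req <- FALSE
  for (p in parents) if (isTRUE(p$req)) { req <- TRUE; break }
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- if (req) parents else list()
  n$grad_fn <- if (req) grad_fn else NULL
  n$req <- req
  class(n) <- "ag_node"
  n
}

#' Create a constant (non-trainable) autograd node
#' @param value numeric array, matrix or vector
#' @keywords internal
ag_const <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$grad_fn <- NULL
  n$req <- FALSE
  class(n) <- "ag_node"
  n
}

#' Create a trainable parameter node
#' @param value initial numeric array
#' @keywords internal
ag_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$grad_fn <- NULL
  n$req <- TRUE
  class(n) <- "ag_node"
  n
}

# nodes are the only environments that flow through the ops, so an
# environment test is a sufficient (and much cheaper) identity check
is_ag <- function(x) is.environment(x)
as_ag <- function(x) if (is.environment(x)) x else ag_const(x)

ag_value <- function(x) x$value

# per-traversal visitation stamps (cheaper than environment-identity keys)
.ag_stamp <- local({
  counter <- 0
  function() {
    counter <<- counter + 1
    counter
  }
})

# Topological order by iterative DFS (post-order), restricted to the
# gradient-requiring subgraph. Marks nodes with a traversal stamp.
ag_topo <- function(root) {
  stamp <- .ag_stamp()
  order <- vector("list", 256L)
  n_ord <- 0L
  stack <- vector("list", 256L)
  n_st <- 1L
  stack[[1L]] <- list(node = root, stage = 1L)
  while (n_st > 0L) {
    top <- stack[[n_st]]
    n_st <- n_st - 1L
    node <- top$node
    if (top$stage == 1L) {
      if (identical(node$.seen, stamp)) next
      node$.seen <- stamp
      n_st <- n_st + 1L
      if (n_st > length(stack)) stack <- c(stack, vector("list", length(stack)))
      stack[[n_st]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (isTRUE(p$req) && !identical(p$.seen, stamp)) {
          n_st <- n_st + 1L
          if (n_st > length(stack)) stack <- c(stack, vector("list", length(stack)))
          stack[[n_st]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  order[seq_len(n_ord)]
}

#' Backpropagate gradients from a scalar node
#'
#' Accumulates into each reachable node's `$grad` (gradients are summed, so
#' per-sample backward passes within a batch accumulate into parameters).
#' @param root scalar-valued node
#' @param seed gradient seed, default 1
#' @keywords internal
ag_backward <- function(root, seed = 1) {
  if (length(root$value) != 1L)
    stop("ag_backward expects a scalar root node")
  if (!isTRUE(root$req)) return(invisible(NULL))
  order <- ag_topo(root)
  root$grad <- add_grad(root$grad, seed)
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad_fn) || is.null(node$grad)) next
    grads <- node$grad_fn(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      g <- grads[[j]]
      if (is.null(g) || !isTRUE(ps[[j]]$req)) next
      ps[[j]]$grad <- add_grad(ps[[j]]$grad, g)
    }
    if (!identical(node, root)) node$grad <- NULL  # free intermediates
  }
  invisible(NULL)
}

add_grad <- function(cur, g) if (is.null(cur)) g else cur + g

#' Zero the gradients of a list of parameter nodes
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag_node(a$value + b$value, list(a, b), function(g) {
    list(collapse_to(g, a$value), collapse_to(g, b$value))
  })
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag_node(a$value - b$value, list(a, b), function(g) {
    list(collapse_to(g, a$value), collapse_to(-g, b$value))
  })
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag_node(a$value * b$value, list(a, b), function(g) {
    list(collapse_to(g * b$value, a$value), collapse_to(g * a$value, b$value))
  })
}

# collapse a broadcast gradient back to the shape of `target` (only the
# scalar-vs-array broadcast is supported here; shaped broadcasts have
# dedicated ops below)
collapse_to <- function(g, target) {
  if (length(target) == 1L && length(g) != 1L) return(sum(g))
  g
}

ag_scale <- function(a, k) {  # multiply by a fixed numeric scalar
  a <- as_ag(a)
  new_ag_node(a$value * k, list(a), function(g) list(g * k))
}

# ---- activations -----------------------------------------------------------

ag_relu <- function(a) {
  a <- as_ag(a)
  mask <- a$value > 0
  new_ag_node(a$value * mask, list(a), function(g) list(g * mask))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  s <- 1 / (1 + exp(-a$value))
  new_ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_softplus <- function(a) {
  a <- as_ag(a)
  x <- a$value
  # numerically stable softplus and its derivative (the logistic function)
  v <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  new_ag_node(v, list(a), function(g) list(g / (1 + exp(-x))))
}

ag_gelu <- function(a) {
  a <- as_ag(a)
  x <- a$value
  ph <- stats::pnorm(x)
  new_ag_node(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

ag_exp <- function(a) {
  a <- as_ag(a)
  v <- exp(a$value)
  new_ag_node(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  a <- as_ag(a)
  new_ag_node(log(a$value), list(a), function(g) list(g / a$value))
}

ag_abs <- function(a) {
  a <- as_ag(a)
  s <- sign(a$value)
  new_ag_node(abs(a$value), list(a), function(g) list(g * s))
}

# ---- reductions ------------------------------------------------------------

ag_mean <- function(a) {
  a <- as_ag(a)
  n <- length(a$value)
  d <- dim(a$value)
  new_ag_node(mean(a$value), list(a), function(g) {
    list(if (is.null(d)) rep(g / n, n) else array(g / n, dim = d))
  })
}

ag_sum <- function(a) {
  a <- as_ag(a)
  d <- dim(a$value)
  new_ag_node(sum(a$value), list(a), function(g) {
    list(if (is.null(d)) rep(g, length(a$value)) else array(g, dim = d))
  })
}

# mean over spatial dims of an (H, W, C) map -> length-C vector (GAP)
ag_gap <- function(a) {
  a <- as_ag(a)
  d <- dim(a$value)
  hw <- d[1] * d[2]
  v <- colMeans(matrix(a$value, hw, d[3]))
  new_ag_node(v, list(a), function(g) {
    list(array(rep(g, each = hw) / hw, dim = d))
  })
}

# mean over channels of an (H, W, C) map -> (H, W) matrix
ag_channel_mean <- function(a) {
  a <- as_ag(a)
  d <- dim(a$value)
  v <- matrix(rowMeans(matrix(a$value, d[1] * d[2], d[3])), d[1], d[2])
  new_ag_node(v, list(a), function(g) {
    list(array(as.vector(g) / d[3], dim = d))
  })
}

# ---- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), crossprod(a$value, g))
  })
}

# y = x W + b for row-matrix x (n, d_in), W (d_in, d_out), b length d_out
ag_dense <- function(x, W, b = NULL) {
  x <- as_ag(x); W <- as_ag(W)
  xv <- x$value
  if (is.null(dim(xv))) xv <- matrix(xv, 1L)
  out <- xv %*% W$value
  if (!is.null(b)) {
    b <- as_ag(b)
    out <- sweep(out, 2L, b$value, `+`)
    new_ag_node(out, list(x, W, b), function(g) {
      if (is.null(dim(g))) g <- matrix(g, 1L)
      gx <- g %*% t(W$value)
      if (is.null(dim(x$value))) gx <- as.vector(gx)
      list(gx, crossprod(xv, g), colSums(g))
    })
  } else {
    new_ag_node(out, list(x, W), function(g) {
      if (is.null(dim(g))) g <- matrix(g, 1L)
      gx <- g %*% t(W$value)
      if (is.null(dim(x$value))) gx <- as.vector(gx)
      list(gx, crossprod(xv, g))
    })
  }
}

ag_transpose <- function(a) {
  a <- as_ag(a)
  new_ag_node(t(a$value), list(a), function(g) list(t(g)))
}

# row-wise softmax of a matrix
ag_softmax_rows <- function(a) {
  a <- as_ag(a)
  x <- a$value
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  new_ag_node(s, list(a), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

# select columns of a matrix; backward scatters into place
ag_cols <- function(a, idx) {
  a <- as_ag(a)
  new_ag_node(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, idx] <- g
    list(out)
  })
}

# select rows of a matrix
ag_rows <- function(a, idx) {
  a <- as_ag(a)
  new_ag_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[idx, ] <- g
    list(out)
  })
}

ag_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_ag)
  vals <- lapply(nodes, ag_value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_ag_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ag_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_ag)
  vals <- lapply(nodes, ag_value)
  heights <- vapply(vals, function(v) if (is.null(dim(v))) 1L else nrow(v), 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  new_ag_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) {
      gj <- g[starts[j]:ends[j], , drop = FALSE]
      if (is.null(dim(vals[[j]]))) as.vector(gj) else gj
    })
  })
}

# ---- token <-> grid reshaping ---------------------------------------------

# tokens (Np, D) in row-major raster order -> (gh, gw, D) map
ag_tokens_to_grid <- function(a, gh, gw) {
  a <- as_ag(a)
  x <- a$value
  if (nrow(x) != gh * gw) stop("token count does not match grid size")
  D <- ncol(x)
  # token n (1-based) sits at grid row r = (n-1) %/% gw + 1, col = (n-1) %% gw + 1
  perm <- matrix(seq_len(gh * gw), gh, gw, byrow = TRUE)  # [r, c] -> token index
  v <- array(x[as.vector(perm), ], dim = c(gh, gw, D))
  new_ag_node(v, list(a), function(g) {
    gm <- matrix(g, gh * gw, D)           # rows in column-major (r fastest)
    out <- matrix(0, gh * gw, D)
    out[as.vector(perm), ] <- gm
    list(out)
  })
}

# (gh, gw, D) map -> tokens (Np, D) in row-major raster order
ag_grid_to_tokens <- function(a) {
  a <- as_ag(a)
  d <- dim(a$value)
  gh <- d[1]; gw <- d[2]; D <- d[3]
  perm <- matrix(seq_len(gh * gw), gh, gw, byrow = TRUE)
  m <- matrix(a$value, gh * gw, D)
  out <- matrix(0, gh * gw, D)
  out[as.vector(perm), ] <- m
  new_ag_node(out, list(a), function(g) {
    list(array(g[as.vector(perm), ], dim = d))
  })
}

# ---- feature-map ops -------------------------------------------------------

# add per-channel bias to (H, W, C)
ag_bias_hwc <- function(x, b) {
  x <- as_ag(x); b <- as_ag(b)
  d <- dim(x$value)
  v <- x$value + rep(b$value, each = d[1] * d[2])
  new_ag_node(v, list(x, b), function(g) {
    list(g, colSums(matrix(g, d[1] * d[2], d[3])))
  })
}

# per-channel affine y[,,c] = x[,,c] * s[c] + t[c]
ag_channel_affine <- function(x, s, t) {
  x <- as_ag(x); s <- as_ag(s); t <- as_ag(t)
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- x$value * rep(s$value, each = hw) + rep(t$value, each = hw)
  new_ag_node(v, list(x, s, t), function(g) {
    gm <- matrix(g, hw, d[3])
    xm <- matrix(x$value, hw, d[3])
    list(g * rep(s$value, each = hw), colSums(gm * xm), colSums(gm))
  })
}

# gate an (H, W, C) map by a per-channel vector in (0,1): y[,,c] = x[,,c]*v[c]
ag_gate_channels <- function(x, v) {
  x <- as_ag(x); v <- as_ag(v)
  d <- dim(x$value)
  hw <- d[1] * d[2]
  out <- x$value * rep(v$value, each = hw)
  new_ag_node(out, list(x, v), function(g) {
    gm <- matrix(g, hw, d[3])
    xm <- matrix(x$value, hw, d[3])
    list(g * rep(v$value, each = hw), colSums(gm * xm))
  })
}

# gate an (H, W, C) map by a spatial (H, W) map: y[,,c] = x[,,c]*m
ag_gate_spatial <- function(x, m) {
  x <- as_ag(x); m <- as_ag(m)
  d <- dim(x$value)
  mv <- as.vector(m$value)
  out <- x$value * array(mv, dim = d)
  new_ag_node(out, list(x, m), function(g) {
    gs <- matrix(rowSums(matrix(g * x$value, d[1] * d[2], d[3])), d[1], d[2])
    list(g * array(mv, dim = d), gs)
  })
}

# concatenate two (H, W, C) maps along channels
ag_concat_channels <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  da <- dim(a$value); db <- dim(b$value)
  v <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  new_ag_node(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# nearest-neighbour upsampling of (H, W, C) by integer factor
ag_upsample <- function(a, factor = 2L) {
  a <- as_ag(a)
  d <- dim(a$value)
  ri <- rep(seq_len(d[1]), each = factor)
  ci <- rep(seq_len(d[2]), each = factor)
  v <- a$value[ri, ci, , drop = FALSE]
  new_ag_node(v, list(a), function(g) {
    # sum each factor x factor block, vectorized via a permuted reshape
    acc <- g
    dim(acc) <- c(factor, d[1], factor, d[2], d[3])  # (f, H, f, W, C)
    acc <- aperm(acc, c(2, 4, 5, 1, 3))
    list(array(rowSums(matrix(acc, d[1] * d[2] * d[3], factor * factor)),
               dim = d))
  })
}

# average pool (H, W, C) by integer factor (used by test stubs and heads)
ag_avgpool <- function(a, factor = 2L) {
  a <- as_ag(a)
  d <- dim(a$value)
  oh <- d[1] %/% factor; ow <- d[2] %/% factor
  x <- a$value[seq_len(oh * factor), seq_len(ow * factor), , drop = FALSE]
  dim(x) <- c(factor, oh, factor, ow, d[3])
  x <- aperm(x, c(2, 4, 5, 1, 3))
  v <- array(rowMeans(matrix(x, oh * ow * d[3], factor * factor)),
             dim = c(oh, ow, d[3]))
  new_ag_node(v, list(a), function(g) {
    gg <- array(0, dim = dim(a$value))
    up <- g[rep(seq_len(oh), each = factor), rep(seq_len(ow), each = factor), ,
            drop = FALSE] / (factor * factor)
    gg[seq_len(oh * factor), seq_len(ow * factor), ] <- up
    list(gg)
  })
}

# ---- 2-D convolution --------------------------------------------------------

# im2col for x (H, W, C): returns list(cols, dims); block order is
# (channel fastest, then kernel row, then kernel col), matching
# aperm(w, c(3, 1, 2, 4)) flattening.
conv_im2col <- function(x, kh, kw, stride, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (pad > 0) {
    xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, C))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  oh <- (Hp - kh) %/% stride + 1L
  ow <- (Wp - kw) %/% stride + 1L
  cols <- matrix(0, oh * ow, kh * kw * C)
  blk <- 0L
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    slab <- xp[seq.int(i, by = stride, length.out = oh),
               seq.int(j, by = stride, length.out = ow), , drop = FALSE]
    cols[, blk + seq_len(C)] <- matrix(slab, oh * ow, C)
    blk <- blk + C
  }
  list(cols = cols, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
}

#' 2-D convolution node: x (H, W, Cin), w (kh, kw, Cin, Cout)
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  x <- as_ag(x); w <- as_ag(w)
  xd <- dim(x$value)
  wd <- dim(w$value)
  if (xd[3] != wd[3]) stop("conv2d: input channels do not match kernel")
  ic <- conv_im2col(x$value, wd[1], wd[2], stride, pad)
  W2 <- matrix(aperm(w$value, c(3, 1, 2, 4)), wd[1] * wd[2] * wd[3], wd[4])
  out2 <- ic$cols %*% W2
  bnode <- if (is.null(b)) NULL else as_ag(b)
  if (!is.null(bnode)) out2 <- sweep(out2, 2L, bnode$value, `+`)
  out <- array(out2, dim = c(ic$oh, ic$ow, wd[4]))
  parents <- if (is.null(bnode)) list(x, w) else list(x, w, bnode)
  node <- new_ag_node(out, parents, function(g) {
    g2 <- matrix(g, ic$oh * ic$ow, wd[4])
    dW2 <- crossprod(ic$cols, g2)
    dw <- aperm(array(dW2, dim = c(wd[3], wd[1], wd[2], wd[4])), c(2, 3, 1, 4))
    dcols <- tcrossprod(g2, W2)
    dxp <- array(0, dim = c(ic$Hp, ic$Wp, wd[3]))
    blk <- 0L
    for (j in seq_len(wd[2])) for (i in seq_len(wd[1])) {
      ii <- seq.int(i, by = stride, length.out = ic$oh)
      jj <- seq.int(j, by = stride, length.out = ic$ow)
      dxp[ii, jj, ] <- dxp[ii, jj, , drop = FALSE] +
        array(dcols[, blk + seq_len(wd[3])], dim = c(ic$oh, ic$ow, wd[3]))
      blk <- blk + wd[3]
    }
    dx <- if (pad > 0) dxp[pad + seq_len(xd[1]), pad + seq_len(xd[2]), , drop = FALSE] else dxp
    if (is.null(bnode)) list(dx, dw) else list(dx, dw, colSums(g2))
  })
  node
}

# ---- layer normalization ---------------------------------------------------

# row-wise layer norm of (N, D) with gain g and bias b (length D)
ag_layernorm <- function(x, gain, bias, eps = 1e-6) {
  x <- as_ag(x); gain <- as_ag(gain); bias <- as_ag(bias)
  xv <- x$value
  D <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gain$value, `*`), 2L, bias$value, `+`)
  new_ag_node(out, list(x, gain, bias), function(g) {
    gg <- sweep(g, 2L, gain$value, `*`)  # d/dxhat
    # per-row backward through normalization
    m1 <- rowMeans(gg)
    m2 <- rowMeans(gg * xhat)
    dx <- inv * (gg - m1 - xhat * m2)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# per-channel affine on a length-C vector (or 1 x C matrix): y = x * s + t
ag_vec_affine <- function(x, s, t) {
  x <- as_ag(x); s <- as_ag(s); t <- as_ag(t)
  to_vec <- function(g) if (is.matrix(g)) colSums(g) else g
  new_ag_node(x$value * s$value + t$value, list(x, s, t), function(g) {
    list(g * s$value, to_vec(g * x$value), to_vec(g))
  })
}

# ---- losses ----------------------------------------------------------------

# mean absolute error between node and constant target
ag_l1 <- function(pred, target) {
  pred <- as_ag(pred)
  tv <- if (is_ag(target)) target$value else target
  diff <- pred$value - tv
  n <- length(diff)
  s <- sign(diff)
  new_ag_node(mean(abs(diff)), list(pred), function(g) {
    gr <- g * s / n
    dim(gr) <- dim(pred$value)
    list(gr)
  })
}

# geometric mean of k positive scalar loss nodes, computed in log space;
# losses below eps are clamped (a zero loss would zero every gradient).
ag_geometric_mean <- function(nodes, eps = 1e-8, warn = TRUE) {
  nodes <- lapply(nodes, as_ag)
  vals <- vapply(nodes, function(n) as.numeric(n$value), 0)
  if (any(vals <= eps) && warn)
    warning("geometric loss: task loss clamped to ", eps, call. = FALSE)
  cl <- pmax(vals, eps)
  k <- length(cl)
  L <- exp(mean(log(cl)))
  new_ag_node(L, nodes, function(g) {
    lapply(seq_len(k), function(j) {
      if (vals[j] <= eps) 0 else g * L / (k * cl[j])
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
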