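# Monocular depth prediction with a transformer encoder.
#
# Pipeline: a convolutional patch embedder abstracts the RGB image into
# Np = H*W/p^2 tokens of dimension D (p is the embedder's total stride) and
# adds a trainable position embedding; a stack of pre-norm transformer
# blocks (multi-head self-attention + MLP, LayerNorm, residual connections)
# processes the tokens while preserving token count and dimension; tapped
# stages are reassembled into image-like feature maps at four scales and a
# RefineNet-style decoder progressively fuses them (coarse to fine, x2
# upsampling + residual conv units) into a dense non-negative depth map in
# centimeters at input resolution.

#' Depth model configuration
#'
#' @param input_size (H, W) of the RGB input; both must be divisible by
#'   `patch`
#' @param patch total stride of the convolutional patch embedder (sampling
#'   rate p); token count is Np = H*W/p^2
#' @param embed_dim token dimension D, constant across encoder stages
#' @param n_blocks number of transformer blocks
#' @param n_heads attention heads; must divide `embed_dim`
#' @param taps indices of the blocks whose outputs feed the decoder
#'   (coarsest-last); default 4 evenly spaced stages
#' @param reassemble_factors spatial resampling factor per tap relative to
#'   the token grid (4 = x4 upsample ... 0.5 = stride-2 conv), fine-to-coarse
#' @param dec_ch decoder channel width
#' @param head_ch channel width of the refinement head
#' @param depth_scale output scale in cm: depth = depth_scale * softplus(z),
#'   keeping predictions non-negative and metric
#' @param readout keep a readout token through the encoder (discarded at
#'   reassembly)
#' @param loss depth training loss: `"l1"` (masked mean absolute error, cm)
#'   or `"ssi"` (scale-and-shift-invariant L1)
#' @return a `depth_config` list
#' @export
depth_model_config <- function(input_size = c(64, 64), patch = 16,
                               embed_dim = 64, n_blocks = 4, n_heads = 4,
                               taps = NULL,
                               reassemble_factors = c(4, 2, 1, 0.5),
                               dec_ch = 32, head_ch = 16, depth_scale = 40,
                               readout = TRUE, loss = c("l1", "ssi")) {
  if (is.null(taps))
    taps <- unique(round(seq_len(4) * n_blocks / 4))
  if (length(taps) < 1 || max(taps) > n_blocks)
    stop("depth_model_config: taps must index into the blocks")
  if (embed_dim %% n_heads != 0)
    stop("depth_model_config: embed_dim must be divisible by n_heads")
  if (length(reassemble_factors) != length(taps))
    reassemble_factors <- reassemble_factors[seq_along(taps)]
  structure(list(input_size = as.integer(input_size), patch = as.integer(patch),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 taps = as.integer(taps),
                 reassemble_factors = reassemble_factors,
                 dec_ch = as.integer(dec_ch), head_ch = as.integer(head_ch),
                 depth_scale = depth_scale, readout = isTRUE(readout),
                 loss = match.arg(loss)),
            class = "depth_config")
}

#' Build a depth prediction model
#'
#' @param config a [depth_model_config()]
#' @param seed seed for weight initialization
#' @return a `depth_model` list of layers and parameters
#' @export
build_depth_model <- function(config = depth_model_config(), seed = 1L) {
  with_seed(seed, {
    p <- config$patch
    D <- config$embed_dim
    n_down <- as.integer(round(log2(p)))
    if (2^n_down != p) stop("build_depth_model: patch must be a power of 2")
    chans <- pmin(D, as.integer(D / 2^rev(seq_len(n_down) - 1)))
    chans <- pmax(chans, 8L)
    chans[n_down] <- D
    stem <- list()
    cin <- 3L
    for (i in seq_len(n_down)) {
      stem[[i]] <- layer_conv2d(cin, chans[i], k = 3L, stride = 2L, pad = 1L)
      cin <- chans[i]
    }
    gh <- config$input_size[1] %/% p
    gw <- config$input_size[2] %/% p
    np <- gh * gw
    pos <- ag_param(matrix(stats::rnorm(np * D, sd = 0.02), np, D))
    readout <- if (config$readout)
      ag_param(matrix(stats::rnorm(D, sd = 0.02), 1, D)) else NULL

    blocks <- lapply(seq_len(config$n_blocks), function(i)
      build_transformer_block(D, config$n_heads))

    reass <- lapply(seq_along(config$taps), function(i) {
      f <- config$reassemble_factors[i]
      r <- list(proj = layer_conv2d(D, config$dec_ch, k = 1L, pad = 0L),
                factor = f)
      if (f < 1) r$down <- layer_conv2d(config$dec_ch, config$dec_ch, k = 3L,
                                        stride = as.integer(round(1 / f)),
                                        pad = 1L)
      r
    })

    dec <- config$dec_ch
    rcu <- function() layer_conv2d(dec, dec, k = 3L, pad = 1L)
    n_maps <- length(config$taps)
    decoder <- list(
      rcu_in = lapply(seq_len(n_maps), function(i) rcu()),
      rcu_out = lapply(seq_len(max(n_maps - 1L, 1L)), function(i) rcu()),
      head1 = layer_conv2d(dec, config$head_ch, k = 3L, pad = 1L),
      head2 = layer_conv2d(config$head_ch, config$head_ch, k = 3L, pad = 1L),
      head3 = layer_conv2d(config$head_ch, 1L, k = 1L, pad = 0L)
    )
    # calibrated output init: small final weights, bias placing the initial
    # prediction near a typical plate distance (~85% of the output scale)
    decoder$head3$w$value <- decoder$head3$w$value * 0.05
    decoder$head3$b$value <- log(expm1(0.85))
    structure(list(config = config, stem = stem, pos = pos, readout = readout,
                   blocks = blocks, reass = reass, decoder = decoder),
              class = "depth_model")
  })
}

build_transformer_block <- function(D, n_heads) {
  list(ln1 = layer_layernorm(D),
       Wq = layer_dense(D, D, gain = 1), Wk = layer_dense(D, D, gain = 1),
       Wv = layer_dense(D, D, gain = 1), Wo = layer_dense(D, D, gain = 1),
       ln2 = layer_layernorm(D),
       mlp1 = layer_dense(D, 4L * D), mlp2 = layer_dense(4L * D, D),
       n_heads = n_heads, dim = D)
}

# ---- forward pieces (autograd-node level) ----------------------------------

embed_forward <- function(model, rgb_node) {
  cfg <- model$config
  x <- rgb_node
  for (ly in model$stem) x <- ag_relu(ly$fwd(x))
  tokens <- ag_grid_to_tokens(x)                       # (Np, D), raster order
  tokens <- ag_add(tokens, model$pos)
  if (!is.null(model$readout)) tokens <- ag_rbind(list(model$readout, tokens))
  tokens
}

msa_forward <- function(block, x) {
  D <- block$dim
  h <- block$n_heads
  dh <- D %/% h
  q <- block$Wq$fwd(x); k <- block$Wk$fwd(x); v <- block$Wv$fwd(x)
  outs <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- (i - 1L) * dh + seq_len(dh)
    qi <- ag_cols(q, idx); ki <- ag_cols(k, idx); vi <- ag_cols(v, idx)
    a <- ag_softmax_rows(ag_scale(ag_matmul(qi, ag_transpose(ki)), 1 / sqrt(dh)))
    outs[[i]] <- ag_matmul(a, vi)
  }
  block$Wo$fwd(ag_cbind(outs))
}

block_forward <- function(block, x) {
  x <- ag_add(x, msa_forward(block, block$ln1$fwd(x)))
  ag_add(x, block$mlp2$fwd(ag_gelu(block$mlp1$fwd(block$ln2$fwd(x)))))
}

encoder_forward <- function(model, tokens) {
  taps <- model$config$taps
  tapped <- vector("list", length(taps))
  x <- tokens
  for (b in seq_along(model$blocks)) {
    x <- block_forward(model$blocks[[b]], x)
    hit <- which(taps == b)
    for (t in hit) tapped[[t]] <- x
  }
  tapped
}

reassemble_forward <- function(model, tokens_node, tap_index) {
  cfg <- model$config
  gh <- cfg$input_size[1] %/% cfg$patch
  gw <- cfg$input_size[2] %/% cfg$patch
  x <- tokens_node
  if (!is.null(model$readout)) x <- ag_rows(x, 1L + seq_len(gh * gw))
  grid <- ag_tokens_to_grid(x, gh, gw)
  r <- model$reass[[tap_index]]
  m <- r$proj$fwd(grid)
  if (r$factor > 1) m <- ag_upsample(m, as.integer(r$factor))
  else if (r$factor < 1) m <- r$down$fwd(m)
  m
}

decoder_forward <- function(model, maps) {
  # maps fine-to-coarse; fuse from the coarsest up
  dec <- model$decoder
  n <- length(maps)
  rcu <- function(ly, x) ag_add(x, ly$fwd(ag_relu(x)))
  f <- rcu(dec$rcu_in[[n]], maps[[n]])
  if (n > 1) {
    for (i in seq.int(n - 1L, 1L)) {
      f <- ag_add(rcu(dec$rcu_in[[i]], maps[[i]]), ag_upsample(f, 2L))
      f <- rcu(dec$rcu_out[[i]], f)
    }
  }
  # refinement head up to input resolution
  target <- model$config$input_size[1]
  f <- ag_relu(dec$head1$fwd(ag_upsample(f, 2L)))
  cur <- dim(f$value)[1]
  remaining <- target %/% cur
  if (remaining * cur != target)
    stop("decoder: feature resolution does not divide input size")
  if (remaining > 1) f <- ag_upsample(f, as.integer(remaining))
  f <- ag_relu(dec$head2$fwd(f))
  z <- dec$head3$fwd(f)
  ag_scale(ag_softplus(z), model$config$depth_scale)
}

depth_forward <- function(model, rgb) {
  cfg <- model$config
  d <- dim(rgb)
  if (d[1] %% cfg$patch != 0 || d[2] %% cfg$patch != 0)
    stop("input size must be divisible by the patch stride")
  rgb_node <- ag_const(rgb - 0.5)
  tokens <- embed_forward(model, rgb_node)
  tapped <- encoder_forward(model, tokens)
  maps <- lapply(seq_along(tapped), function(i)
    reassemble_forward(model, tapped[[i]], i))
  decoder_forward(model, maps)
}

# ---- exported operations ---------------------------------------------------

#' Embed an RGB image into a token sequence
#'
#' Convolutional patch embedding (total stride p) followed by addition of
#' the trainable position embedding; a readout token is prepended when the
#' model was built with one. Errors if the image size is not divisible by p.
#'
#' @param model a `depth_model`
#' @param rgb H x W x 3 array in `[0,1]`
#' @return token matrix ((Np + readout) x D)
#' @export
hybrid_embed <- function(model, rgb) {
  cfg <- model$config
  d <- dim(rgb)
  if (d[1] %% cfg$patch != 0 || d[2] %% cfg$patch != 0)
    stop("hybrid_embed: image size must be divisible by the patch stride")
  ag_value(embed_forward(model, ag_const(rgb - 0.5)))
}

#' Apply one transformer block to a token matrix
#'
#' Pre-norm residual composition: `t <- t + MSA(LN(t))` then
#' `t <- t + MLP(LN(t))`. Token count and dimension are preserved.
#'
#' @param block one element of `model$blocks`
#' @param tokens numeric (N, D) matrix
#' @param return_attention also return the per-head attention matrices
#' @return token matrix, or list(tokens, attention) when requested
#' @export
transformer_block <- function(block, tokens, return_attention = FALSE) {
  x <- ag_const(tokens)
  if (return_attention) {
    att <- list()
    ln <- block$ln1$fwd(x)
    D <- block$dim; h <- block$n_heads; dh <- D %/% h
    q <- block$Wq$fwd(ln); k <- block$Wk$fwd(ln); v <- block$Wv$fwd(ln)
    outs <- vector("list", h)
    for (i in seq_len(h)) {
      idx <- (i - 1L) * dh + seq_len(dh)
      a <- ag_softmax_rows(ag_scale(
        ag_matmul(ag_cols(q, idx), ag_transpose(ag_cols(k, idx))), 1 / sqrt(dh)))
      att[[i]] <- a$value
      outs[[i]] <- ag_matmul(a, ag_cols(v, idx))
    }
    y <- ag_add(x, block$Wo$fwd(ag_cbind(outs)))
    y <- ag_add(y, block$mlp2$fwd(ag_gelu(block$mlp1$fwd(block$ln2$fwd(y)))))
    return(list(tokens = ag_value(y), attention = att))
  }
  ag_value(block_forward(block, x))
}

#' Reassemble a token sequence into an image-like feature map
#'
#' Functional form of the reassembly operation: tokens in row-major raster
#' order are placed back on their (gh, gw) grid, optionally projected by a
#' `D x D'` matrix, and resampled by `factor` (nearest-neighbour upsampling
#' for factor > 1, average pooling for factor < 1).
#'
#' @param tokens numeric (Np, D) matrix without the readout token
#' @param grid_shape integer (gh, gw) with gh*gw = Np
#' @param factor spatial resampling factor (default 1 = placement only)
#' @param proj optional D x D' projection matrix
#' @return (gh*factor, gw*factor, D') array
#' @export
reassemble_tokens <- function(tokens, grid_shape, factor = 1, proj = NULL) {
  gh <- grid_shape[1]; gw <- grid_shape[2]
  if (nrow(tokens) != gh * gw)
    stop("reassemble_tokens: token count does not match grid size")
  x <- ag_const(tokens)
  if (!is.null(proj)) x <- ag_matmul(x, ag_const(proj))
  g <- ag_tokens_to_grid(x, gh, gw)
  if (factor > 1) g <- ag_upsample(g, as.integer(factor))
  else if (factor < 1) g <- ag_avgpool(g, as.integer(round(1 / factor)))
  ag_value(g)
}

#' Inverse of token placement (grid back to raster-order tokens)
#' @param grid (gh, gw, D) array
#' @return (gh*gw, D) token matrix in row-major raster order
#' @export
tokens_from_grid <- function(grid) {
  ag_value(ag_grid_to_tokens(ag_const(grid)))
}

#' Decode a list of image-like maps into a depth map
#'
#' RefineNet-style progressive fusion: starting from the coarsest map, each
#' step passes the finer map through a residual conv unit, adds the x2
#' upsampled coarser path, and refines; a convolutional head upsamples to
#' input resolution and a softplus keeps depth non-negative.
#'
#' @param model a `depth_model`
#' @param maps list of (H_s, W_s, dec_ch) arrays, fine-to-coarse, resolutions
#'   strictly decreasing
#' @return H x W depth matrix (cm)
#' @export
refine_decode <- function(model, maps) {
  if (!length(maps)) stop("refine_decode: need at least one map")
  chs <- vapply(maps, function(m) dim(m)[3], 1L)
  if (any(chs != model$config$dec_ch))
    stop("refine_decode: inconsistent channel counts")
  res <- vapply(maps, function(m) dim(m)[1], 1L)
  if (length(res) > 1 && any(diff(res) >= 0))
    stop("refine_decode: resolutions must decrease toward the coarse end")
  nodes <- lapply(maps, ag_const)
  out <- ag_value(decoder_forward(model, nodes))
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Predict a depth map from an RGB image
#'
#' Full composition: hybrid embedding, transformer encoder with tapped
#' stages, reassembly of each tap, and the refinement decoder. Deterministic
#' in evaluation mode.
#'
#' @param model a `depth_model`
#' @param rgb H x W x 3 array in `[0,1]`
#' @return H x W non-negative depth matrix (cm)
#' @export
predict_depth <- function(model, rgb) {
  out <- ag_value(depth_forward(model, rgb))
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Depth training loss
#'
#' Default: masked mean absolute error in cm. The scale-and-shift-invariant
#' variant first aligns the prediction to the ground truth by least squares
#' (a, b) and then takes the masked mean absolute error of the aligned
#' prediction; it decouples the loss from the global metric scale.
#'
#' @param pred predicted depth (matrix, cm)
#' @param gt ground-truth depth, same shape
#' @param mask logical matrix of valid pixels (default all)
#' @param type `"l1"` or `"ssi"`
#' @return scalar loss
#' @export
depth_train_loss <- function(pred, gt, mask = NULL, type = c("l1", "ssi")) {
  type <- match.arg(type)
  if (!identical(dim(pred), dim(gt))) stop("depth_train_loss: shape mismatch")
  keep <- if (is.null(mask)) rep(TRUE, length(gt)) else as.vector(mask)
  if (!any(keep)) stop("depth_train_loss: empty mask")
  p <- as.vector(pred)[keep]
  d <- as.vector(gt)[keep]
  if (type == "ssi") {
    fit <- stats::lm.fit(cbind(p, 1), d)
    p <- fit$coefficients[1] * p + fit$coefficients[2]
  }
  mean(abs(p - d))
}

# node-level masked L1 used by the depth training loop
ag_masked_l1 <- function(pred_node, gt, mask = NULL) {
  keep <- if (is.null(mask)) rep(TRUE, length(gt)) else as.vector(mask)
  if (!any(keep)) stop("depth loss: empty mask")
  pv <- as.vector(pred_node$value)
  diff <- (pv - as.vector(gt)) * keep
  n <- sum(keep)
  s <- sign(diff)
  new_ag_node(sum(abs(diff)) / n, list(pred_node), function(g) {
    gr <- g * s / n
    dim(gr) <- dim(pred_node$value)
    list(gr)
  })
}
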