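# Two-stream RGB-D fusion network for nutrition estimation.
#
# Twin convolutional backbones extract five-level feature pyramids from the
# RGB image and the (replicated, normalized) depth map. At each level the
# cross-modal attention block (CAB) gates both modalities by a shared
# channel-attention vector CA = Sig(Conv1x1(GAP(R + D))) and a shared
# spatial-attention map SA = Sig(Conv3x3(Mean_c(R + D))) — a
# fuse-enhance-fuse scheme — and projects the concatenated gated features
# back to the level's channel count. A multi-scale fusion cascade
# F_i = C_i + Res_i(F_{i-1}) (Res_i: stride-2 bottleneck residual block)
# carries shallow detail into the deep representation F_4, which feeds
# global average pooling, a shared FC layer and five single-output heads
# (calories, mass, fat, carb, protein).

#' Fusion model configuration
#'
#' @param input_size (H, W) of the model input; at least 32 pixels per side
#'   (each backbone stage halves the resolution with ceiling rounding, e.g.
#'   336 x 448 gives an 11 x 14 level-4 map)
#' @param channels channel count per pyramid level (strides 2,4,8,16,32)
#' @param head_dim width of the shared fully connected layer before the five
#'   task heads (2048 in the full-scale profile)
#' @param streams `"rgbd"` (both), `"rgb"` or `"depth"` (single-stream
#'   ablations)
#' @param attention use the CAB attention gating; FALSE gives the direct
#'   concatenation fusion
#' @param multiscale use the multi-scale fusion cascade; FALSE regresses
#'   from the deepest fused map alone
#' @param literal_cascade use the literal form F_i = C_i + Res_i(C_{i-1})
#'   instead of the progressive F_i = C_i + Res_i(F_{i-1})
#' @param shared_head one shared FC then five 1-output heads (default);
#'   FALSE builds five fully separate head stacks
#' @param depth_norm `"fixed"` divides depth by `depth_scale` (preserves the
#'   metric scale); `"minmax"` rescales each depth map to `[0,1]`
#' @param depth_scale fixed depth normalizer in cm (typically the camera
#'   height)
#' @return a `fusion_config` list
#' @export
fusion_model_config <- function(input_size = c(64, 64),
                                channels = c(8, 16, 32, 64, 128),
                                head_dim = 64,
                                streams = c("rgbd", "rgb", "depth"),
                                attention = TRUE, multiscale = TRUE,
                                literal_cascade = FALSE, shared_head = TRUE,
                                depth_norm = c("fixed", "minmax"),
                                depth_scale = 40) {
  streams <- match.arg(streams)
  if (length(channels) != 5) stop("fusion_model_config: need 5 channel counts")
  if (any(input_size < 32))
    stop("fusion_model_config: input size must be at least 32 pixels")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 head_dim = as.integer(head_dim), streams = streams,
                 attention = isTRUE(attention), multiscale = isTRUE(multiscale),
                 literal_cascade = isTRUE(literal_cascade),
                 shared_head = isTRUE(shared_head),
                 depth_norm = match.arg(depth_norm),
                 depth_scale = depth_scale),
            class = "fusion_config")
}

build_backbone <- function(channels) {
  cin <- 3L
  stages <- list()
  for (i in seq_along(channels)) {
    stages[[i]] <- list(conv = layer_conv2d(cin, channels[i], k = 3L,
                                            stride = 2L, pad = 1L),
                        norm = layer_channel_norm(channels[i]))
    cin <- channels[i]
  }
  stages
}

build_cab <- function(c) {
  list(ca_fc = layer_dense(c, c),
       ca_norm = layer_vec_norm(c),
       sa_conv = layer_conv2d(1L, 1L, k = 3L, pad = 1L),
       sa_norm = layer_channel_norm(1L),
       fuse = layer_conv2d(2L * c, c, k = 1L, pad = 0L))
}

build_res_block <- function(cin, cout) {
  mid <- max(cout %/% 4L, 4L)
  list(reduce = layer_conv2d(cin, mid, k = 1L, pad = 0L),
       rnorm = layer_channel_norm(mid),
       conv = layer_conv2d(mid, mid, k = 3L, stride = 2L, pad = 1L),
       cnorm = layer_channel_norm(mid),
       expand = layer_conv2d(mid, cout, k = 1L, pad = 0L),
       enorm = layer_channel_norm(cout),
       shortcut = layer_conv2d(cin, cout, k = 1L, stride = 2L, pad = 0L))
}

#' Build a fusion model
#'
#' @param config a [fusion_model_config()]
#' @param seed seed for weight initialization
#' @return a `fusion_model` list; `y_scale` holds the per-task output scale
#'   (set from training labels by the training loop, identity by default)
#' @export
build_fusion_model <- function(config = fusion_model_config(), seed = 1L) {
  with_seed(seed, {
    ch <- config$channels
    m <- list(config = config)
    m$backbone_rgb <- if (config$streams != "depth") build_backbone(ch) else NULL
    m$backbone_depth <- if (config$streams != "rgb") build_backbone(ch) else NULL
    if (config$streams == "rgbd")
      m$cab <- lapply(ch, build_cab)
    if (config$streams == "rgbd" && config$multiscale)
      m$res <- lapply(seq_len(4), function(i) build_res_block(ch[i], ch[i + 1]))
    c4 <- ch[5]
    if (config$shared_head) {
      m$fc <- layer_dense(c4, config$head_dim)
      m$heads <- lapply(1:5, function(i) layer_dense(config$head_dim, 1L))
    } else {
      m$heads <- lapply(1:5, function(i)
        list(fc = layer_dense(c4, config$head_dim),
             out = layer_dense(config$head_dim, 1L)))
    }
    m$y_scale <- rep(1, 5)
    class(m) <- "fusion_model"
    m
  })
}

# ---- node-level forward ----------------------------------------------------

backbone_forward <- function(stages, x) {
  maps <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    x <- ag_relu(stages[[i]]$norm$fwd(stages[[i]]$conv$fwd(x)))
    maps[[i]] <- x
  }
  maps
}

prep_depth_input <- function(depth, config) {
  d <- if (config$depth_norm == "minmax") {
    rng <- range(depth)
    if (rng[2] > rng[1]) (depth - rng[1]) / (rng[2] - rng[1]) else depth * 0
  } else {
    # fixed metric encoding: height above the table plane (depth_scale is
    # the camera height) expressed at food-height scale (a tenth of the
    # camera height), so centimetre-level relief spans the input range
    # instead of being squashed by the camera distance
    (config$depth_scale - depth) / (0.1 * config$depth_scale)
  }
  array(d, dim = c(dim(depth), 3L)) - 0.5
}

ca_forward <- function(cab, Rn, Dn) {
  g <- ag_gap(ag_add(Rn, Dn))
  z <- cab$ca_norm$fwd(cab$ca_fc$fwd(g))
  # ca_fc yields a 1 x c matrix; flatten to a vector for the affine norm
  ag_sigmoid(ag_relu(z))
}

sa_forward <- function(cab, Rn, Dn) {
  m <- ag_channel_mean(ag_add(Rn, Dn))
  d <- dim(m$value)
  m3 <- new_ag_node(array(m$value, dim = c(d, 1L)), list(m),
                    function(g) list(matrix(g, d[1], d[2])))
  s <- cab$sa_norm$fwd(cab$sa_conv$fwd(m3))
  out <- ag_sigmoid(ag_relu(s))
  # back to an (H, W) matrix
  new_ag_node(matrix(out$value, d[1], d[2]), list(out),
              function(g) list(array(g, dim = c(d, 1L))))
}

cab_forward <- function(cab, Rn, Dn, attention = TRUE) {
  if (attention) {
    ca <- ca_forward(cab, Rn, Dn)
    ca_vec <- new_ag_node(as.vector(ca$value), list(ca),
                          function(g) list(matrix(g, 1L)))
    sa <- sa_forward(cab, Rn, Dn)
    Rg <- ag_gate_spatial(ag_gate_channels(Rn, ca_vec), sa)
    Dg <- ag_gate_spatial(ag_gate_channels(Dn, ca_vec), sa)
  } else {
    Rg <- Rn; Dg <- Dn
  }
  cab$fuse$fwd(ag_concat_channels(Rg, Dg))
}

res_forward <- function(res, x) {
  h <- ag_relu(res$rnorm$fwd(res$reduce$fwd(x)))
  h <- ag_relu(res$cnorm$fwd(res$conv$fwd(h)))
  h <- res$enorm$fwd(res$expand$fwd(h))
  ag_relu(ag_add(h, res$shortcut$fwd(x)))
}

heads_forward <- function(model, f4_node) {
  h <- ag_gap(f4_node)
  cfg <- model$config
  if (cfg$shared_head) {
    shared <- ag_relu(model$fc$fwd(h))
    lapply(model$heads, function(hd) hd$fwd(shared))
  } else {
    lapply(model$heads, function(hd) hd$out$fwd(ag_relu(hd$fc$fwd(h))))
  }
}

fusion_forward <- function(model, rgb, depth = NULL, force_attention_ones = FALSE) {
  cfg <- model$config
  if (cfg$streams != "rgb" && is.null(depth))
    stop("fusion model: depth input required in '", cfg$streams, "' mode")
  pyr_r <- if (!is.null(model$backbone_rgb))
    backbone_forward(model$backbone_rgb, ag_const(rgb - 0.5)) else NULL
  pyr_d <- if (!is.null(model$backbone_depth))
    backbone_forward(model$backbone_depth, ag_const(prep_depth_input(depth, cfg)))
  else NULL
  if (cfg$streams == "rgb") {
    f4 <- pyr_r[[5]]
  } else if (cfg$streams == "depth") {
    f4 <- pyr_d[[5]]
  } else {
    att <- cfg$attention && !force_attention_ones
    C <- lapply(1:5, function(i)
      cab_forward(model$cab[[i]], pyr_r[[i]], pyr_d[[i]], attention = att))
    if (cfg$multiscale) {
      f <- C[[1]]
      for (i in 2:5) {
        prev <- if (cfg$literal_cascade) C[[i - 1]] else f
        f <- ag_add(C[[i]], res_forward(model$res[[i - 1]], prev))
      }
      f4 <- f
    } else {
      f4 <- C[[5]]
    }
  }
  heads_forward(model, f4)
}

# ---- exported operations ---------------------------------------------------

#' Extract a five-level feature pyramid
#'
#' Runs one backbone stream over an input image. Level i has stride 2^(i+1)
#' relative to the input and the configured channel count. The depth stream
#' receives a single-channel depth map, which is normalized (fixed scale by
#' default) and replicated to three channels before the stem.
#'
#' @param model a `fusion_model`
#' @param image H x W x 3 RGB array in `[0,1]` (rgb stream) or H x W depth
#'   matrix in cm (depth stream)
#' @param stream `"rgb"` or `"depth"`
#' @return list of 5 feature arrays, strides 2, 4, 8, 16, 32
#' @export
extract_pyramid <- function(model, image, stream = c("rgb", "depth")) {
  stream <- match.arg(stream)
  if (stream == "rgb") {
    if (is.null(model$backbone_rgb)) stop("model has no RGB stream")
    if (length(dim(image)) != 3L || dim(image)[3] != 3L)
      stop("extract_pyramid: RGB input must be H x W x 3")
    x <- ag_const(image - 0.5)
    lapply(backbone_forward(model$backbone_rgb, x), ag_value)
  } else {
    if (is.null(model$backbone_depth)) stop("model has no depth stream")
    if (length(dim(image)) > 2L)
      stop("extract_pyramid: depth input must be a single-channel matrix")
    x <- ag_const(prep_depth_input(image, model$config))
    lapply(backbone_forward(model$backbone_depth, x), ag_value)
  }
}

#' Channel attention of a cross-modal attention block
#'
#' `CA = Sig(ReLU(Norm(Conv1x1(GAP(R + D)))))`: global average pooling of
#' the element-wise sum, a 1x1 convolution (acting on the pooled vector)
#' with normalization and rectification, then a sigmoid. Values lie in
#' (0, 1) and broadcast over space.
#'
#' @param cab one element of `model$cab`
#' @param R,D same-shape (H, W, c) feature arrays
#' @return length-c channel attention vector
#' @export
channel_attention <- function(cab, R, D) {
  if (!identical(dim(R), dim(D))) stop("channel_attention: shape mismatch")
  as.vector(ag_value(ca_forward(cab, ag_const(R), ag_const(D))))
}

#' Spatial attention of a cross-modal attention block
#'
#' `SA = Sig(ReLU(Norm(Conv3x3(Mean_c(R + D)))))`: the channel-wise mean of
#' the element-wise sum, smoothed by a padding-preserving 3x3 convolution
#' with normalization and rectification, then a sigmoid. Values lie in
#' (0, 1) and broadcast over channels.
#'
#' @inheritParams channel_attention
#' @return (H, W) spatial attention matrix
#' @export
spatial_attention <- function(cab, R, D) {
  if (!identical(dim(R), dim(D))) stop("spatial_attention: shape mismatch")
  ag_value(sa_forward(cab, ag_const(R), ag_const(D)))
}

#' Cross-modal attention fusion of one pyramid level
#'
#' Gates both modalities by the shared channel and spatial attention
#' (`R * CA * SA`, `D * CA * SA`, broadcast pixel-wise products),
#' concatenates along channels and projects back to c channels with a 1x1
#' convolution. With `attention = FALSE` the gating is skipped, which is
#' exactly the direct concatenation fusion baseline (identical to forcing
#' CA and SA to one everywhere).
#'
#' @inheritParams channel_attention
#' @param attention apply the attention gating (default TRUE)
#' @return (H, W, c) fused feature array
#' @export
cab_fuse <- function(cab, R, D, attention = TRUE) {
  if (!identical(dim(R), dim(D))) stop("cab_fuse: shape mismatch")
  ag_value(cab_forward(cab, ag_const(R), ag_const(D), attention = attention))
}

#' Multi-scale fusion cascade
#'
#' Progressively combines the fused pyramid `{C_i}` from shallow to deep:
#' `F_0 = C_0`, `F_i = C_i + Res_i(F_{i-1})`, where each `Res_i` halves the
#' resolution and maps the channel count of level i-1 to level i, and
#' returns the final representation F_4. `res_override` substitutes plain
#' functions (numeric array in, numeric array out) for the residual blocks,
#' which supports stub-based verification of the cascade arithmetic.
#'
#' @param model a `fusion_model` with a multi-scale cascade (ignored when
#'   `res_override` is given)
#' @param fused list of fused feature arrays C_0..C_4 (fine to coarse)
#' @param res_override optional list of functions replacing the Res blocks
#' @param literal use the literal form `F_i = C_i + Res_i(C_{i-1})`
#' @return the deepest fused representation F_4 (array)
#' @export
multiscale_fuse <- function(model = NULL, fused, res_override = NULL,
                            literal = FALSE) {
  n <- length(fused)
  if (n < 2) stop("multiscale_fuse: need at least two levels")
  apply_res <- function(i, x) {
    if (!is.null(res_override)) return(res_override[[i]](x))
    ag_value(res_forward(model$res[[i]], ag_const(x)))
  }
  f <- fused[[1]]
  for (i in 2:n) {
    prev <- if (literal) fused[[i - 1]] else f
    ri <- apply_res(i - 1L, prev)
    if (!identical(dim(ri), dim(fused[[i]])))
      stop("multiscale_fuse: Res output shape does not match level ", i - 1)
    f <- fused[[i]] + ri
  }
  f
}

#' Multi-task nutrition heads
#'
#' Global average pooling of the final representation, a shared FC layer,
#' and five independent single-output heads, returned in the fixed order
#' calories, mass, fat, carb, protein (times the model's per-task output
#' scale).
#'
#' @param model a `fusion_model`
#' @param f4 final fused representation (H, W, c4) array
#' @return named numeric vector of 5 predictions
#' @export
nutrition_heads <- function(model, f4) {
  outs <- heads_forward(model, ag_const(f4))
  v <- vapply(outs, function(o) as.numeric(ag_value(o)), 0) * model$y_scale
  stats::setNames(v, NUTRIENTS)
}

#' Predict the nutrition of one dish
#'
#' Full fusion forward pass: pyramid extraction for the active streams,
#' per-level cross-modal fusion, the multi-scale cascade, and the
#' multi-task heads. Deterministic in evaluation mode. In `"rgbd"` mode a
#' depth map must be supplied (from a sensor, the synthetic generator, or
#' [predict_depth()] for the end-to-end monocular path).
#'
#' @param model a `fusion_model`
#' @param rgb H x W x 3 RGB array in `[0,1]`
#' @param depth H x W depth matrix in cm (required unless streams = "rgb")
#' @param force_attention_ones bypass the attention gating at prediction
#'   time (CA and SA treated as all ones)
#' @return named numeric vector: calories, mass, fat, carb, protein
#' @export
predict_nutrition <- function(model, rgb, depth = NULL,
                              force_attention_ones = FALSE) {
  outs <- fusion_forward(model, rgb, depth,
                         force_attention_ones = force_attention_ones)
  v <- vapply(outs, function(o) as.numeric(ag_value(o)), 0) * model$y_scale
  stats::setNames(v, NUTRIENTS)
}
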