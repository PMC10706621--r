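# Shared fixtures: tiny model configurations, small rendered scenes and a
# finite-difference gradient checker for the autodiff engine.

nv <- asNamespace("nutrivision")

tiny_depth_config <- function(...) {
  depth_model_config(input_size = c(32, 32), patch = 16, embed_dim = 16,
                     n_blocks = 2, n_heads = 2, taps = c(1, 2),
                     reassemble_factors = c(2, 1), dec_ch = 8, head_ch = 4,
                     depth_scale = 40, ...)
}

tiny_fusion_config <- function(input_size = c(32, 32), ...) {
  fusion_model_config(input_size = input_size, channels = c(4, 6, 8, 10, 12),
                      head_dim = 8, depth_scale = 35, ...)
}

tiny_scene <- function(seed = 1, image_size = c(32, 32), noise = FALSE,
                       n_blobs = 2) {
  random_scene(image_size = image_size, seed = seed, n_blobs = n_blobs,
               noise = scene_noise(noise))
}

# central-difference gradient check: f maps a parameter node value to a
# scalar loss through the graph built by `build(x_node)`
check_gradient <- function(value, build, eps = 1e-5, tol = 1e-4) {
  x <- nv$ag_param(value)
  loss <- build(x)
  nv$ag_backward(loss)
  got <- x$grad
  num <- array(0, dim = dim(value) %||% length(value))
  flat <- as.vector(value)
  for (i in seq_along(flat)) {
    vp <- value; vp[i] <- vp[i] + eps
    vm <- value; vm[i] <- vm[i] - eps
    xp <- nv$ag_param(vp); xm <- nv$ag_param(vm)
    num[i] <- (as.numeric(build(xp)$value) - as.numeric(build(xm)$value)) / (2 * eps)
  }
  scale <- max(abs(num), abs(got), 1e-8)
  expect_lt(max(abs(as.vector(got) - as.vector(num))) / scale, tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
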