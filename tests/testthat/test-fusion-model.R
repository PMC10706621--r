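# Fusion module contracts: pyramid shapes, attention ranges and hand
# evaluations, the attention-bypass identity, the multi-scale cascade stub
# oracle, and the multi-task heads.

rand_map <- function(h, w, c, seed) {
  set.seed(seed)
  array(rnorm(h * w * c), dim = c(h, w, c))
}

test_that("pyramids follow the stride/channel law and twin streams agree", {
  cfg <- tiny_fusion_config()
  m <- build_fusion_model(cfg, seed = 1)
  rgb <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  pyr <- extract_pyramid(m, rgb, "rgb")
  for (i in 1:5) {
    side <- as.integer(32 / 2^i)
    expect_identical(dim(pyr[[i]]), c(side, side, cfg$channels[i]))
  }
  # strictly decreasing spatial size
  sizes <- vapply(pyr, function(p) dim(p)[1], 1L)
  expect_true(all(diff(sizes) < 0))
  # identical weights on identical inputs give identical pyramids
  m$backbone_depth <- m$backbone_rgb
  fake_depth_as_rgb <- extract_pyramid(m, rgb, "rgb")
  expect_identical(fake_depth_as_rgb, pyr)
  # full-scale shape arithmetic: 336x448 input gives an 11x14 level-4 map
  m2 <- build_fusion_model(tiny_fusion_config(input_size = c(336, 448)),
                           seed = 1)
  rgb2 <- array(0.5, dim = c(336, 448, 3))
  pyr2 <- extract_pyramid(m2, rgb2, "rgb")
  expect_identical(dim(pyr2[[5]])[1:2], c(11L, 14L))
})

test_that("channel attention matches the hand evaluation of its chain", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 2)
  cab <- m$cab[[1]]
  # identity 1x1 conv, unit-scale/zero-shift norm (the build default)
  cab$ca_fc$W$value <- diag(ncol(cab$ca_fc$W$value))
  cab$ca_fc$b$value[] <- 0
  # zero inputs -> sigmoid(0) = 0.5 per channel
  z <- array(0, dim = c(8, 8, 4))
  expect_equal(channel_attention(cab, z, z), rep(0.5, 4), tolerance = 1e-12)
  # constant-c inputs per channel -> sigmoid(relu(2c))
  for (const in c(-0.7, 0.3, 1.2)) {
    x <- array(const, dim = c(8, 8, 4))
    expect_equal(channel_attention(cab, x, x),
                 rep(plogis(max(2 * const, 0)), 4), tolerance = 1e-12)
  }
  # range strictly inside (0, 1) on random inputs, any weights
  m2 <- build_fusion_model(tiny_fusion_config(), seed = 3)
  for (i in 1:5) {
    h <- 32 %/% 2^i; c_i <- m2$config$channels[i]
    R <- rand_map(h, h, c_i, 100 + i); D <- rand_map(h, h, c_i, 200 + i)
    ca <- channel_attention(m2$cab[[i]], R, D)
    expect_equal(length(ca), c_i)
    expect_true(all(ca > 0 & ca < 1))
  }
})

test_that("spatial attention matches the channel-mean oracle and its zero case", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 4)
  cab <- m$cab[[2]]
  cab$sa_conv$b$value[] <- 0
  z <- array(0, dim = c(8, 8, 6))
  expect_equal(spatial_attention(cab, z, z), matrix(0.5, 8, 8), tolerance = 1e-12)
  R <- rand_map(8, 8, 6, 41); D <- rand_map(8, 8, 6, 42)
  sa <- spatial_attention(cab, R, D)
  expect_identical(dim(sa), c(8L, 8L))
  expect_true(all(sa > 0 & sa < 1))
  # the channel-mean step agrees with a per-pixel loop oracle
  got <- nv$ag_channel_mean(nv$ag_const(R + D))$value
  want <- matrix(0, 8, 8)
  for (r in 1:8) for (cc in 1:8) want[r, cc] <- mean(R[r, cc, ] + D[r, cc, ])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("CAB output keeps the level shape and bypass equals direct fusion", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 5)
  for (i in 1:5) {
    h <- 32 %/% 2^i; c_i <- m$config$channels[i]
    R <- rand_map(h, h, c_i, 300 + i); D <- rand_map(h, h, c_i, 400 + i)
    C <- cab_fuse(m$cab[[i]], R, D)
    expect_identical(dim(C), dim(R))
    # all-ones attention reduces CAB to concat + 1x1 conv, exactly
    direct <- cab_fuse(m$cab[[i]], R, D, attention = FALSE)
    gated <- nv$ag_value(nv$cab_forward(
      m$cab[[i]], nv$ag_const(R), nv$ag_const(D), attention = FALSE))
    expect_identical(direct, gated)
  }
})

test_that("constructed 1x1 fusion weights recover the attention-gated RGB branch", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 6)
  cab <- m$cab[[3]]
  c_i <- m$config$channels[3]
  # fusion conv takes the first half (the gated R features) identically
  w <- array(0, dim = c(1, 1, 2 * c_i, c_i))
  for (k in seq_len(c_i)) w[1, 1, k, k] <- 1
  cab$fuse$w$value <- w
  cab$fuse$b$value[] <- 0
  R <- rand_map(4, 4, c_i, 77)
  D <- array(0, dim = c(4, 4, c_i))
  ca <- channel_attention(cab, R, D)
  sa <- spatial_attention(cab, R, D)
  want <- R * rep(ca, each = 16) * array(as.vector(sa), dim = dim(R))
  expect_equal(cab_fuse(cab, R, D), want, tolerance = 1e-12)
})

test_that("the multi-scale cascade matches a hand-computed stub cascade", {
  # Res blocks replaced by exact x2 average-pool + channel tiling stubs
  c1 <- 2; c2 <- 4
  C0 <- rand_map(4, 4, c1, 91)
  C1 <- rand_map(2, 2, c2, 92)
  stub <- function(x) {
    pooled <- nv$ag_value(nv$ag_avgpool(nv$ag_const(x), 2L))
    array(pooled[, , rep(seq_len(dim(x)[3]), length.out = c2)],
          dim = c(dim(pooled)[1:2], c2))
  }
  got <- multiscale_fuse(fused = list(C0, C1), res_override = list(stub))
  want <- C1 + stub(C0)
  expect_equal(got, want, tolerance = 1e-12)
  # literal variant differs only in its input to Res (2 levels: identical)
  expect_equal(multiscale_fuse(fused = list(C0, C1),
                               res_override = list(stub), literal = TRUE),
               want, tolerance = 1e-12)
})

test_that("cascade output keeps the deepest level's shape; zero C with bias-free blocks gives zero", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 7)
  fused <- lapply(1:5, function(i)
    rand_map(32 %/% 2^i, 32 %/% 2^i, m$config$channels[i], 500 + i))
  f4 <- multiscale_fuse(m, fused)
  expect_identical(dim(f4), dim(fused[[5]]))
  # zero inputs through bias-free residual blocks stay zero
  for (rb in m$res) {
    rb$reduce$b$value[] <- 0; rb$conv$b$value[] <- 0
    rb$expand$b$value[] <- 0; rb$shortcut$b$value[] <- 0
    rb$rnorm$t$value[] <- 0; rb$cnorm$t$value[] <- 0; rb$enorm$t$value[] <- 0
  }
  zeros <- lapply(fused, function(f) f * 0)
  expect_equal(max(abs(multiscale_fuse(m, zeros))), 0)
})

test_that("nutrition heads return 5 ordered outputs; GAP matches the spatial mean", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 8)
  f4 <- rand_map(1, 1, m$config$channels[5], 61)
  p <- nutrition_heads(m, f4)
  expect_identical(names(p), c("calories", "mass", "fat", "carb", "protein"))
  x <- rand_map(4, 4, 3, 62)
  expect_equal(nv$ag_gap(nv$ag_const(x))$value,
               apply(x, 3, mean), tolerance = 1e-12)
  # zero representation with zero biases gives zero predictions
  m$fc$b$value[] <- 0
  for (hd in m$heads) hd$b$value[] <- 0
  expect_equal(unname(nutrition_heads(m, f4 * 0)), rep(0, 5))
})

test_that("full model: bypass identity, determinism, and missing-depth error", {
  s <- render_dish(tiny_scene(seed = 9))
  m <- build_fusion_model(tiny_fusion_config(), seed = 9)
  p1 <- predict_nutrition(m, s$rgb, s$depth)
  expect_identical(predict_nutrition(m, s$rgb, s$depth), p1)
  # forcing attention to ones equals the attention-free config with the
  # same weights (the direct-fusion counterpart)
  forced <- predict_nutrition(m, s$rgb, s$depth, force_attention_ones = TRUE)
  m_direct <- m
  m_direct$config$attention <- FALSE
  expect_identical(predict_nutrition(m_direct, s$rgb, s$depth), forced)
  expect_error(predict_nutrition(m, s$rgb), "depth")
})

test_that("gradients reach every parameter of both streams", {
  s <- render_dish(tiny_scene(seed = 10))
  m <- build_fusion_model(tiny_fusion_config(), seed = 10)
  params <- nv$collect_params(m)
  nv$ag_zero_grad(params)
  outs <- nv$fusion_forward(m, s$rgb, s$depth)
  loss <- nv$ag_geometric_mean(lapply(outs, function(o)
    nv$ag_abs(nv$ag_sub(o, 2))), warn = FALSE)
  nv$ag_backward(loss)
  n_missing <- sum(vapply(params, function(p) is.null(p$grad), TRUE))
  expect_equal(n_missing, 0)
  n_zero <- sum(vapply(params, function(p) all(p$grad == 0), TRUE))
  # a handful of dead-ReLU channels are possible, but no whole branch
  expect_lt(n_zero / length(params), 0.1)
})

test_that("batch order permutation permutes predictions identically", {
  m <- build_fusion_model(tiny_fusion_config(), seed = 11)
  samples <- lapply(1:3, function(i) render_dish(tiny_scene(seed = 20 + i)))
  preds <- lapply(samples, function(s) predict_nutrition(m, s$rgb, s$depth))
  perm <- c(3, 1, 2)
  preds_perm <- lapply(samples[perm], function(s)
    predict_nutrition(m, s$rgb, s$depth))
  expect_identical(preds_perm, preds[perm])
})
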