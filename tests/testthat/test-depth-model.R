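# Depth module contracts: token arithmetic, transformer block behavior,
# reassembly bijection, decoder shape/non-negativity, and the training loss.

test_that("token count follows Np = H*W/p^2 and indivisible sizes error", {
  m <- build_depth_model(depth_model_config(input_size = c(64, 64), patch = 16,
                                            embed_dim = 32, n_blocks = 2,
                                            n_heads = 2, taps = c(1, 2),
                                            reassemble_factors = c(2, 1)),
                         seed = 1)
  rgb <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  tok <- hybrid_embed(m, rgb)
  expect_equal(nrow(tok), 64 * 64 / 16^2 + 1)  # + readout token
  expect_equal(ncol(tok), 32)
  m2 <- build_depth_model(tiny_depth_config(readout = FALSE), seed = 1)
  rgb2 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_equal(nrow(hybrid_embed(m2, rgb2)), 4)
  expect_error(hybrid_embed(m2, array(0.5, dim = c(33, 32, 3))), "divisible")
})

test_that("encoder stages preserve token count and dimension", {
  m <- build_depth_model(tiny_depth_config(), seed = 2)
  rgb <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  tok <- hybrid_embed(m, rgb)
  out <- tok
  for (b in m$blocks) {
    out <- transformer_block(b, out)
    expect_identical(dim(out), dim(tok))
  }
})

test_that("a transformer block with zeroed sublayer outputs is the identity", {
  m <- build_depth_model(tiny_depth_config(), seed = 3)
  blk <- m$blocks[[1]]
  blk$Wo$W$value[] <- 0; blk$Wo$b$value[] <- 0
  blk$mlp2$W$value[] <- 0; blk$mlp2$b$value[] <- 0
  x <- matrix(rnorm(5 * 16), 5, 16)
  expect_equal(transformer_block(blk, x), x, tolerance = 1e-12)
})

test_that("attention weights are row-stochastic", {
  m <- build_depth_model(tiny_depth_config(), seed = 4)
  x <- matrix(rnorm(5 * 16), 5, 16)
  res <- transformer_block(m$blocks[[1]], x, return_attention = TRUE)
  for (A in res$attention) {
    expect_true(all(A > 0))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
  }
})

test_that("token reassembly recovers grid ordering and scales shapes", {
  # one-hot tokens: token n carries its own index; placement must put token
  # n at raster position n, and the inverse must recover the ordering
  tok <- diag(12)
  g <- reassemble_tokens(tok, c(3, 4))
  for (r in 1:3) for (cc in 1:4)
    expect_equal(which(g[r, cc, ] == 1), (r - 1) * 4 + cc)
  expect_identical(tokens_from_grid(g), tok)
  # identity projection at grid scale returns the placed tokens
  tok2 <- matrix(rnorm(12 * 6), 12, 6)
  g2 <- reassemble_tokens(tok2, c(3, 4), factor = 1, proj = diag(6))
  expect_equal(tokens_from_grid(g2), tok2, tolerance = 1e-12)
  # doubling factor doubles both spatial dims
  g3 <- reassemble_tokens(matrix(rnorm(16 * 4), 16, 4), c(4, 4), factor = 2)
  expect_identical(dim(g3)[1:2], c(8L, 8L))
})

test_that("the decoder yields a full-resolution non-negative depth map", {
  cfg <- tiny_depth_config()
  m <- build_depth_model(cfg, seed = 5)
  rgb <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  d <- predict_depth(m, rgb)
  expect_identical(dim(d), c(32L, 32L))
  expect_true(all(d >= 0))
  # eval-mode determinism
  expect_identical(predict_depth(m, rgb), d)
  # degenerate single-map input still decodes to input resolution
  maps <- list(array(rnorm(8 * 8 * cfg$dec_ch), dim = c(8, 8, cfg$dec_ch)))
  d1 <- refine_decode(m, maps)
  expect_identical(dim(d1), c(32L, 32L))
  expect_true(all(d1 >= 0))
  expect_error(refine_decode(m, list(array(0, dim = c(8, 8, 3)))), "channel")
})

test_that("depth training loss matches its examples and the masked oracle", {
  gt <- matrix(runif(64, 20, 35), 8, 8)
  expect_equal(depth_train_loss(gt, gt), 0)
  expect_equal(depth_train_loss(gt + 1, gt), 1, tolerance = 1e-12)
  set.seed(31)
  pred <- gt + rnorm(64)
  mask <- matrix(runif(64) > 0.3, 8, 8)
  expect_equal(depth_train_loss(pred, gt, mask),
               mean(abs(pred[mask] - gt[mask])), tolerance = 1e-12)
  expect_error(depth_train_loss(pred, gt, mask & FALSE), "mask")
  # scale-and-shift-invariant variant is zero for affinely related maps
  expect_equal(depth_train_loss(2 * gt + 3, gt, type = "ssi"), 0,
               tolerance = 1e-8)
})

test_that("perfect depth predictions give AbsRel 0, RMSE 0 and all deltas 1", {
  s <- render_dish(tiny_scene(seed = 6))
  m <- depth_metrics(s$depth, s$depth, mask = s$depth > 0)
  expect_equal(m$absrel, 0)
  expect_equal(m$rmse, 0)
  expect_equal(unname(m$delta), c(1, 1, 1))
})

test_that("depth training decreases the loss over the first 50 steps", {
  ds <- make_dataset(8, image_size = c(32, 32), seed = 12,
                     noise = scene_noise(FALSE), camera_height = 35)
  ck <- train_depth_stage(ds, tiny_depth_config(), steps = 50, batch_size = 4,
                          lr = 2e-3, seed = 1, validate_every = 0)
  expect_lt(mean(tail(ck$history, 5)), mean(head(ck$history, 5)))
})

test_that("depth checkpoints round-trip through save/load", {
  m <- build_depth_model(tiny_depth_config(), seed = 7)
  ck <- structure(list(model = m, history = NULL, best_val_absrel = NA_real_),
                  class = "depth_checkpoint")
  path <- file.path(tempdir(), "nv_depth_ck")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  rgb <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_equal(predict_depth(ck2$model, rgb), predict_depth(m, rgb),
               tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".yaml")))
})
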