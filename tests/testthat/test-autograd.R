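# The training engine is validated against central finite differences: for
# every operation used by the models, analytic gradients must agree with
# numeric ones on random inputs.

test_that("elementwise, reduction and activation gradients match finite differences", {
  set.seed(11)
  x0 <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_mul(x, nv$ag_const(x0 + 1))))
  check_gradient(x0, function(x) nv$ag_sum(nv$ag_sigmoid(x)))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_softplus(x)))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_gelu(x)))
  check_gradient(x0 + 3, function(x) nv$ag_mean(nv$ag_log(x)))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_gap(x)))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_channel_mean(x)))
  # relu checked away from the kink
  xr <- x0 + sign(x0) * 0.5
  check_gradient(xr, function(x) nv$ag_mean(nv$ag_relu(x)))
})

test_that("matrix operation gradients match finite differences", {
  set.seed(12)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  check_gradient(A, function(x) nv$ag_mean(nv$ag_matmul(x, nv$ag_const(B))))
  check_gradient(B, function(x) nv$ag_mean(nv$ag_matmul(nv$ag_const(A), x)))
  check_gradient(A, function(x) nv$ag_mean(nv$ag_softmax_rows(x)))
  W <- matrix(rnorm(8), 4, 2)
  b <- rnorm(2)
  check_gradient(A, function(x) nv$ag_mean(nv$ag_dense(x, nv$ag_const(W), nv$ag_const(b))))
  check_gradient(W, function(w) nv$ag_mean(nv$ag_dense(nv$ag_const(A), w, nv$ag_const(b))))
  g <- rnorm(4); be <- rnorm(4)
  check_gradient(A, function(x) nv$ag_mean(nv$ag_layernorm(x, nv$ag_const(g), nv$ag_const(be))))
  check_gradient(g, function(x) nv$ag_mean(nv$ag_layernorm(nv$ag_const(A), x, nv$ag_const(be))))
})

test_that("convolution gradients match finite differences for stride and padding variants", {
  set.seed(13)
  for (cfg in list(list(k = 3, stride = 1, pad = 1, cin = 2, cout = 3),
                   list(k = 3, stride = 2, pad = 1, cin = 1, cout = 2),
                   list(k = 1, stride = 1, pad = 0, cin = 3, cout = 2),
                   list(k = 1, stride = 2, pad = 0, cin = 2, cout = 2))) {
    x0 <- array(rnorm(6 * 6 * cfg$cin), dim = c(6, 6, cfg$cin))
    w0 <- array(rnorm(cfg$k^2 * cfg$cin * cfg$cout),
                dim = c(cfg$k, cfg$k, cfg$cin, cfg$cout))
    b0 <- rnorm(cfg$cout)
    check_gradient(x0, function(x)
      nv$ag_mean(nv$ag_conv2d(x, nv$ag_const(w0), nv$ag_const(b0),
                              stride = cfg$stride, pad = cfg$pad)))
    check_gradient(w0, function(w)
      nv$ag_mean(nv$ag_conv2d(nv$ag_const(x0), w, nv$ag_const(b0),
                              stride = cfg$stride, pad = cfg$pad)))
    check_gradient(b0, function(b)
      nv$ag_mean(nv$ag_conv2d(nv$ag_const(x0), nv$ag_const(w0), b,
                              stride = cfg$stride, pad = cfg$pad)))
  }
})

test_that("convolution forward equals a direct nested-loop oracle", {
  set.seed(14)
  x <- array(rnorm(5 * 7 * 2), dim = c(5, 7, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
  b <- rnorm(3)
  got <- nv$ag_conv2d(nv$ag_const(x), nv$ag_const(w), nv$ag_const(b),
                      stride = 1, pad = 1)$value
  xp <- array(0, dim = c(7, 9, 2))
  xp[2:6, 2:8, ] <- x
  want <- array(0, dim = c(5, 7, 3))
  for (oi in 1:5) for (oj in 1:7) for (oc in 1:3) {
    acc <- b[oc]
    for (ki in 1:3) for (kj in 1:3) for (ci in 1:2)
      acc <- acc + xp[oi + ki - 1, oj + kj - 1, ci] * w[ki, kj, ci, oc]
    want[oi, oj, oc] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("upsampling, pooling, gating and concatenation gradients are exact", {
  set.seed(15)
  x0 <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_upsample(x, 2L)))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_avgpool(x, 2L)))
  v0 <- runif(3, 0.2, 0.8)
  m0 <- matrix(runif(16), 4, 4)
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_gate_channels(x, nv$ag_const(v0))))
  check_gradient(v0, function(v) nv$ag_mean(nv$ag_gate_channels(nv$ag_const(x0), v)))
  check_gradient(x0, function(x) nv$ag_mean(nv$ag_gate_spatial(x, nv$ag_const(m0))))
  check_gradient(m0, function(m) nv$ag_mean(nv$ag_gate_spatial(nv$ag_const(x0), m)))
  y0 <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  check_gradient(x0, function(x)
    nv$ag_mean(nv$ag_concat_channels(x, nv$ag_const(y0))))
  check_gradient(y0, function(y)
    nv$ag_mean(nv$ag_concat_channels(nv$ag_const(x0), y)))
})

test_that("token/grid reshaping is a bijection with exact gradients", {
  set.seed(16)
  tok <- matrix(rnorm(12 * 5), 12, 5)
  grid <- nv$ag_tokens_to_grid(nv$ag_const(tok), 3, 4)$value
  back <- nv$ag_grid_to_tokens(nv$ag_const(grid))$value
  expect_identical(back, tok)
  check_gradient(tok, function(x) nv$ag_mean(nv$ag_tokens_to_grid(x, 3, 4)))
  g0 <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  check_gradient(g0, function(x) nv$ag_mean(nv$ag_grid_to_tokens(x)))
})

test_that("geometric-mean loss node has the analytic gradient L/(k*l_i)", {
  ls <- c(1, 2, 4, 8, 16)
  nodes <- lapply(ls, nv$ag_param)
  L <- nv$ag_geometric_mean(nodes, warn = FALSE)
  expect_equal(L$value, 4)
  nv$ag_backward(L)
  for (i in seq_along(ls))
    expect_equal(nodes[[i]]$grad, 4 / (5 * ls[i]), tolerance = 1e-12)
})

test_that("gradients accumulate across backward calls and reset on zero_grad", {
  p <- nv$ag_param(c(1, 2))
  for (r in 1:2) nv$ag_backward(nv$ag_sum(nv$ag_mul(p, p)))
  expect_equal(p$grad, 2 * c(2, 4))
  nv$ag_zero_grad(list(p))
  expect_null(p$grad)
})
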