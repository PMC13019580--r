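test_that("default config reproduces the published layer dimensions", {
  cfg <- model_config()
  expect_equal(cfg$window$backcast, 210L)   # 7 x 30
  expect_equal(cfg$window$horizon, 30L)
  expect_equal(cfg$lstm_units, 256L)
  expect_equal(cfg$fc1_units, 128L)
  expect_equal(cfg$fc2_units, 64L)
  expect_equal(cfg$poly_degree, 3L)
  expect_equal(cfg$fourier_order, 3L)
  expect_equal(cfg$season_period, 90)
  expect_equal(cfg$n_heads, 3L)
  expect_equal(cfg$n_features, 21L)
})

test_that("every published layer row's shapes are asserted on a real forward", {
  # full-size forward on a small batch: each trunk layer's input/output
  # dimensions must match the published table exactly
  cfg <- model_config()
  m <- build_model(cfg, seed = 1)
  B <- 2L
  set.seed(3)
  x0 <- array(rnorm(B * 21 * 210), c(B, 21, 210))
  fw <- pedvol:::model_forward(m, x0, train = FALSE)
  st <- fw$streams
  for (blk in c("trend", "seasonal", "basic1")) {
    cache <- st$cache[[blk]]
    expect_equal(dim(cache$lstm$x), c(B, 21L, 210L))          # LSTM in
    expect_equal(ncol(cache$fc1$x), 256L)                     # LSTM out -> FC in
    expect_equal(ncol(cache$fc1$z), 128L)                     # FC1 out
  }
  expect_equal(ncol(st$cache$trend$fc2$z), 64L)               # FC2 out
  expect_equal(ncol(st$cache$trend$fc3$z), 4L)                # theta (p+1)
  expect_equal(ncol(st$cache$seasonal$fc3$z), 7L)             # theta (2i+1)
  expect_equal(ncol(st$cache$basic1$fc2$z), 30L)              # forecast head
  expect_equal(dim(st$cache$basic2$lstm$x), c(B, 21L, 30L))   # block 2 in
  expect_equal(ncol(st$cache$basic2$fc2$z), 30L)
  # basis projections: backcast to 210, forecast to 30
  expect_equal(dim(st$trend$backcast), c(B, 21L, 210L))
  expect_equal(dim(st$seasonal$backcast), c(B, 21L, 210L))
  expect_equal(dim(st$trend$forecast), c(B, 21L, 30L))
  expect_equal(dim(fw$fused), c(B, 21L, 30L))                 # output layer
  expect_equal(dim(fw$attention$weights), c(B, 3L, 21L, 21L)) # 3 heads F x F
})

test_that("residual conservation holds exactly at every stage", {
  m <- tiny_model(seed = 2)
  set.seed(4)
  L <- m$cfg$window$backcast
  x0 <- array(rnorm(3 * 3 * L), c(3, 3, L))
  st <- stack_forward(m, x0)
  ri <- st$residual_inputs
  expect_identical(ri$x1, ri$x0 - st$trend$backcast)
  expect_identical(ri$x2, ri$x1 - st$seasonal$backcast)
  # telescoping: x0 - (trend + seasonal backcasts) is generic block 1 input
  expect_equal(ri$x2, ri$x0 - st$trend$backcast - st$seasonal$backcast,
               tolerance = 1e-12)
  expect_identical(ri$x3, st$residual1$forecast)
})

test_that("interpretable blocks equal basis %*% theta vs an independent oracle", {
  m <- tiny_model(seed = 6)
  set.seed(8)
  L <- m$cfg$window$backcast; H <- m$cfg$window$horizon
  x0 <- array(rnorm(2 * 3 * L), c(2, 3, L))
  st <- stack_forward(m, x0)
  for (blk in c("trend", "seasonal")) {
    basis <- m$bases[[blk]]
    th <- st[[blk]]$theta
    for (b in 1:2) for (f in 1:3) {
      # independent matrix multiply from the same theta
      expect_equal(st[[blk]]$backcast[b, f, ],
                   as.vector(basis$back %*% th[b, f, ]), tolerance = 1e-6)
      expect_equal(st[[blk]]$forecast[b, f, ],
                   as.vector(basis$fore %*% th[b, f, ]), tolerance = 1e-6)
    }
  }
  # constant theta -> constant backcast and forecast
  th0 <- array(0, dim(st$trend$theta)); th0[, , 1] <- 3.5
  expect_true(all(abs(pedvol:::basis_project(th0, m$bases$trend$back) - 3.5) < 1e-12))
  expect_true(all(abs(pedvol:::basis_project(th0, m$bases$trend$fore) - 3.5) < 1e-12))
})

test_that("attention rows are probability vectors and identical values pass through", {
  m <- tiny_model(seed = 10)
  H <- m$cfg$window$horizon
  set.seed(11)
  streams <- lapply(1:3, function(k) array(rnorm(2 * 3 * H), c(2, 3, H)))
  fu <- attention_fuse(m, streams)
  sums <- apply(fu$weights, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_equal(dim(fu$weights)[2], 3L)
  # all value rows identical -> every head output row equals that value's
  # projection regardless of the attention pattern
  v <- rnorm(H)
  same <- array(rep(v, each = 2 * 3), c(2, 3, H))
  fu2 <- attention_fuse(m, list(same, same, same))
  hc <- fu2$cache$hcache[[1]]
  for (k in 1:3) {
    proj <- matrix(v, 1) %*% m$params$attn[[paste0("h", k)]]$Wv
    expect_equal(hc[[k]]$A %*% hc[[k]]$V,
                 matrix(rep(proj, 3), 3, byrow = TRUE), tolerance = 1e-9)
  }
  expect_error(attention_fuse(m, list(streams[[1]], streams[[2]],
                                      streams[[3]][, 1:2, , drop = FALSE])),
               "shape mismatch")
})

test_that("build is deterministic and eval-mode forward is reproducible", {
  m1 <- tiny_model(seed = 33)
  m2 <- tiny_model(seed = 33)
  expect_identical(pedvol:::flatten_params(m1$params),
                   pedvol:::flatten_params(m2$params))
  set.seed(1)
  x0 <- array(rnorm(2 * 3 * m1$cfg$window$backcast),
              c(2, 3, m1$cfg$window$backcast))
  f1 <- pedvol:::model_forward(m1, x0)$fused
  f2 <- pedvol:::model_forward(m1, x0)$fused
  expect_identical(f1, f2)
})

test_that("zero input with zero-bias init flows zero through the stack", {
  m <- tiny_model(seed = 12)
  L <- m$cfg$window$backcast
  x0 <- array(0, c(1, 3, L))
  st <- stack_forward(m, x0)
  # LSTM of zero input from zero state is zero; dense biases start at zero
  expect_true(all(st$trend$theta == 0))
  expect_true(all(st$trend$backcast == 0))
  expect_true(all(st$residual1$forecast == 0))
  expect_true(all(st$residual2$forecast == 0))
})

test_that("training reduces loss and is seed-reproducible; lr 0 freezes it", {
  p <- random_panel(T_ = 80, F_ = 3, seed = 14)
  sc <- fit_scaler(p)
  w <- make_windows(transform_panel(p, sc), tiny_window())
  m <- tiny_model(seed = 15)
  tc <- train_config(epochs = 5, batch_size = 16, learning_rate = 1e-2, seed = 16)
  fit1 <- train_model(m, w, tc)
  expect_lt(fit1$history$train_loss[5], fit1$history$train_loss[1])
  fit2 <- train_model(m, w, tc)
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
  frozen <- train_model(m, w, train_config(epochs = 3, batch_size = 16,
                                           learning_rate = 0, seed = 16))
  expect_equal(frozen$history$train_loss,
               rep(frozen$history$train_loss[1], 3), tolerance = 1e-12)
  expect_error(train_model(m, list(inputs = array(0, c(0, 8, 3))),
                           tc), "empty|horizon")
})

test_that("attention export is row-stochastic with the right shape", {
  p <- random_panel(T_ = 40, F_ = 3, seed = 17)
  w <- make_windows(p, tiny_window())
  m <- tiny_model(seed = 18)
  a <- export_attention(m, w)
  expect_equal(dim(a), c(3L, 3L, 3L))
  expect_lt(max(abs(apply(a, c(1, 2), sum) - 1)), 1e-6)
  d <- tempfile()
  paths <- write_attention_csv(a, d)
  expect_true(all(file.exists(file.path(d, paste0("attention_head_",
                                                  c("trend", "seasonal", "residual"),
                                                  ".csv")))))
})

test_that("checkpoint round trip restores weights and config exactly", {
  m <- tiny_model(seed = 19)
  d <- tempfile()
  save_checkpoint(m, d)
  m2 <- load_checkpoint(d)
  expect_equal(pedvol:::flatten_params(m2$params),
               pedvol:::flatten_params(m$params), tolerance = 1e-15)
  expect_equal(m2$cfg$window$backcast, m$cfg$window$backcast)
  set.seed(2)
  x0 <- array(rnorm(1 * 3 * m$cfg$window$backcast),
              c(1, 3, m$cfg$window$backcast))
  expect_equal(pedvol:::model_forward(m2, x0)$fused,
               pedvol:::model_forward(m, x0)$fused, tolerance = 1e-12)
})
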