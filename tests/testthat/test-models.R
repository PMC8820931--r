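test_that("pyramid and training configs validate and echo the defaults", {
  cfg <- train_config()
  expect_identical(cfg$batch_size, 8L)
  expect_identical(cfg$epochs, 10L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$drop_rate, 0.01)
  py <- pyramid_config()
  expect_identical(py$scales, c(1L, 2L, 3L, 6L))
  expect_equal(py$stage_weights, rep(1, 4))
  expect_error(pyramid_config(scales = c(2, 2, 3)), "strictly increasing")
  expect_error(pyramid_config(stage_weights = c(1, 2)), "stage_weights")
  expect_error(train_config(drop_rate = 1), "drop_rate")
})

test_that("pooling scales larger than the backbone feature map are rejected", {
  expect_error(build_pspnet(pyramid = pyramid_config(scales = c(1, 2, 3, 12)),
                            input_size = 64L),
               "configuration error")
  # 96x96 input gives 12x12 features, so scale 12 fits
  expect_s3_class(build_pspnet(pyramid = pyramid_config(scales = c(1, 2, 3, 12)),
                               input_size = 96L, backbone_depth = "tiny"),
                  "pspnet")
})

test_that("concatenated channel count is conserved for all studied scale sets", {
  for (scales in list(c(1, 2, 3, 6), c(1, 2, 3, 6, 8, 12), c(2, 3))) {
    py <- pyramid_config(scales = scales, reduced_channels = 8L)
    size <- max(64L, 8L * max(scales))
    m <- build_pspnet(backbone_depth = "tiny", pyramid = py,
                      input_size = size, seed = 2)
    img <- matrix(0.5, size, size)
    fw <- net_forward(m, img)
    expect_identical(dim(fw$taps$psp_concat)[3],
                     as.integer(m$backbone_channels + length(scales) * 8L))
  }
})

test_that("stage weighting is a scalar gain: neutral weights change nothing, doubling doubles", {
  py1 <- pyramid_config(stage_weights = NULL)
  py2 <- pyramid_config(stage_weights = c(1, 1, 1, 1))
  m1 <- tiny_pspnet(seed = 31, pyramid = py1)
  m2 <- tiny_pspnet(seed = 31, pyramid = py2)
  for (rep in 1:10) {
    img <- matrix(runif(64 * 64), 64, 64)
    f1 <- net_forward(m1, img)
    f2 <- net_forward(m2, img)
    expect_identical(f1$out, f2$out)
    expect_identical(f1$taps$psp_concat, f2$taps$psp_concat)
  }
  # doubling one stage weight exactly doubles that stage's block
  py3 <- pyramid_config(stage_weights = c(1, 2, 1, 1))
  m3 <- tiny_pspnet(seed = 31, pyramid = py3)
  img <- matrix(runif(64 * 64), 64, 64)
  b1 <- net_forward(m1, img)$taps$psp_concat
  b3 <- net_forward(m3, img)$taps$psp_concat
  ch <- m1$psp_channel_map$stage_2
  expect_equal(b3[, , ch], 2 * b1[, , ch])
  other <- setdiff(seq_len(dim(b1)[3]), ch)
  expect_identical(b3[, , other], b1[, , other])
})

test_that("a scale-1 stage carries the per-channel global mean everywhere", {
  m <- tiny_pspnet(seed = 12)
  feats <- array(runif(8 * 8 * m$backbone_channels), dim = c(8, 8, m$backbone_channels))
  bundle <- psp_forward(m, feats)
  s1 <- bundle$stage_features$stage_1
  # constant over space (1x1 pooled then upsampled)
  for (k in seq_len(dim(s1)[3]))
    expect_lt(diff(range(s1[, , k])), 1e-12)
  # and equal to the reduction conv applied to the channel means
  W <- m$params$psp.reduce1.W
  b <- m$params$psp.reduce1.b
  mu <- apply(feats, 3, mean)
  expect_equal(as.numeric(s1[1, 1, ]),
               pmax(as.numeric(W %*% mu + b), 0) * m$pyramid$stage_weights[1],
               tolerance = 1e-12)
  # bundle bookkeeping
  expect_identical(dim(bundle$concatenated)[3],
                   as.integer(m$backbone_channels +
                                4L * m$pyramid$reduced_channels))
})

test_that("a constant feature map stays constant through any pooling stage", {
  m <- tiny_pspnet(seed = 4)
  feats <- array(rep(runif(m$backbone_channels), each = 64),
                 dim = c(8, 8, m$backbone_channels))
  bundle <- psp_forward(m, feats)
  for (nm in names(bundle$stage_features)) {
    st <- bundle$stage_features[[nm]]
    for (k in seq_len(dim(st)[3]))
      expect_lt(diff(range(st[, , k])), 1e-9)
  }
})

test_that("residual blocks with zero residual branch and identity shortcut are the identity", {
  l <- pyrexcam:::layer_resblock("rb", 4L, 4L, stride = 1L)
  p <- pyrexcam:::with_seed(1, pyrexcam:::init_layer_params(l))
  p$rb.conv1.W[] <- 0; p$rb.conv1.b[] <- 0
  p$rb.conv2.W[] <- 0; p$rb.conv2.b[] <- 0
  x <- array(abs(rnorm(6 * 6 * 4)), dim = c(6, 6, 4))  # non-negative input
  out <- pyrexcam:::resblock_fw(l, p, x)$out
  expect_equal(out, x)
  expect_false(l$uses_projection)
  expect_true(pyrexcam:::layer_resblock("rb", 4L, 8L)$uses_projection)
  expect_true(pyrexcam:::layer_resblock("rb", 4L, 4L, stride = 2L)$uses_projection)
})

test_that("the decoder upsamples x8 and every stage influences the output", {
  m <- tiny_pspnet(seed = 77)
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- net_forward(m, img)
  expect_identical(dim(fw$out)[1:2], c(64L, 64L))
  expect_identical(dim(fw$taps$backbone)[1:2], c(8L, 8L))
  bw <- net_backward(m, fw$caches, array(1, dim = dim(fw$out)),
                     want_tap_grads = TRUE)
  g <- bw$tap_grads$psp_concat
  for (s in m$pyramid$scales) {
    ch <- m$psp_channel_map[[paste0("stage_", s)]]
    expect_gt(sum(abs(g[, , ch])), 0)
  }
})

test_that("UNet taps cover each decoder resolution and reach the output", {
  u <- build_unet(depth = 4L, seed = 6)
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- net_forward(u, img)
  expect_identical(dim(fw$out)[1:2], c(64L, 64L))
  res <- vapply(fw$taps, function(t) dim(t)[1], integer(1))
  expect_identical(unname(res[paste0("conv_", 1:4)]), c(8L, 16L, 32L, 64L))
  bw <- net_backward(u, fw$caches, array(1, dim = dim(fw$out)),
                     want_tap_grads = TRUE)
  for (tp in u$taps) expect_gt(sum(abs(bw$tap_grads[[tp]])), 0)
  expect_error(build_unet(depth = 1L), "depth")
})

test_that("training is seeded-deterministic and reduces the loss on an overfit run", {
  samples <- tiny_samples(8, seed = 2)
  cfg <- train_config(batch_size = 4L, epochs = 3L, learning_rate = 1e-2,
                      seed = 5L)
  m <- tiny_pspnet(seed = 1)
  r1 <- train_model(m, samples, cfg)
  r2 <- train_model(m, samples, cfg)
  expect_identical(r1$history, r2$history)
  expect_lt(r1$history$loss[3], r1$history$loss[1])
  expect_error(train_model(m, list(), cfg), "empty")
})

test_that("prediction thresholds behave as per-pixel comparisons", {
  m <- tiny_pspnet(seed = 44)
  img <- matrix(runif(64 * 64), 64, 64)
  p0 <- predict(m, img, threshold = 0)
  expect_true(all(p0$mask == 1))
  p1 <- predict(m, img, threshold = 1)
  expect_true(all(p1$mask[p1$prob < 1] == 0))
  pr <- predict(m, img, threshold = 0.5)
  expect_identical(pr$mask, (pr$prob >= 0.5) * 1)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- tiny_pspnet(seed = 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  expect_true(file.exists(file.path(dir, "model.json")))
  m2 <- load_model(path)
  expect_identical(param_checksum(m), param_checksum(m2))
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(predict(m, img)$prob, predict(m2, img)$prob)
})
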