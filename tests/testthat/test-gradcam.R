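test_that("the target score is the spatial sum of the class score map", {
  expect_equal(target_score(matrix(0, 5, 5)), 0)
  m <- matrix(0, 4, 4); m[2, 3] <- 3.5
  expect_equal(target_score(m), 3.5)
  set.seed(1)
  x <- matrix(rnorm(36), 6, 6)
  acc <- 0
  for (i in 1:6) for (j in 1:6) acc <- acc + x[i, j]
  expect_equal(target_score(x), acc)
  r <- matrix(rbinom(36, 1, 0.5), 6, 6)
  expect_equal(target_score(x, restrict = r), sum(x * r))
  expect_error(target_score(x, class_index = 2), "class_index")
})

test_that("attribution weights are spatial gradient means", {
  set.seed(2)
  acts <- array(rnorm(32), dim = c(4, 4, 2))
  grads <- array(0, dim = c(4, 4, 2))
  grads[, , 1] <- 0.7          # constant gradient -> weight 0.7
  grads[, , 2] <- rnorm(16)
  ctx <- cam_context(acts, grads)
  a <- cam_weights(ctx)
  expect_equal(a[1], 0.7)
  expect_equal(a[2], mean(grads[, , 2]))
  zero <- cam_context(acts, array(0, dim = dim(acts)))
  expect_equal(cam_weights(zero), c(0, 0))
  expect_error(cam_context(acts, array(0, dim = c(4, 4, 3))), "shape")
})

test_that("autodiff weights match central finite differences at every tap", {
  net <- toy_net(seed = 3)
  img <- matrix(runif(64, 0, 1), 8, 8)
  fw <- pyrexcam:::seq_forward(net, pyrexcam:::as_tensor(img))
  bw <- pyrexcam:::seq_backward(net, fw$caches,
                                array(1, dim = dim(fw$out)),
                                want_tap_grads = TRUE)
  for (tap in c("tap1", "tap2")) {
    ctx <- cam_context(fw$taps[[tap]], bw$tap_grads[[tap]])
    a_auto <- cam_weights(ctx)
    a_fd <- fd_alpha(net, tap, fw$taps[[tap]])
    denom <- pmax(abs(a_fd), 1e-8)
    expect_lt(max(abs(a_auto - a_fd) / denom), 1e-3)
  }
})

test_that("the localization map is the rectified weighted channel sum", {
  set.seed(4)
  acts <- array(abs(rnorm(48)), dim = c(4, 4, 3))
  grads <- array(rnorm(48), dim = c(4, 4, 3))
  ctx <- cam_context(acts, grads)
  a <- cam_weights(ctx)
  cm <- cam_map(ctx, a)
  # brute-force loop oracle
  raw <- matrix(0, 4, 4)
  for (k in 1:3) for (i in 1:4) for (j in 1:4)
    raw[i, j] <- raw[i, j] + a[k] * acts[i, j, k]
  raw <- pmax(raw, 0)
  expect_equal(cm$values, raw / max(raw))
  expect_equal(cm$raw_max, max(raw))
  # single channel, unit weight: map proportional to the activations
  ctx1 <- cam_context(acts[, , 1, drop = FALSE], grads[, , 1, drop = FALSE])
  cm1 <- cam_map(ctx1, 1)
  expect_equal(cm1$values, acts[, , 1] / max(acts[, , 1]))
  # all-negative weights on positive activations clip to zero
  cmz <- cam_map(ctx, c(-1, -2, -0.5))
  expect_equal(cmz$raw_max, 0)
  expect_true(all(cmz$values == 0))
  expect_error(cam_map(ctx, c(1, 2)), "alpha")
})

test_that("tap-level CAM drivers equal the manual composition", {
  m <- tiny_pspnet(seed = 18)
  img <- generate_phantom(tiny_spec(seed = 5))$image
  fw <- net_forward(m, img)
  # full spatial-sum aggregation
  bw <- net_backward(m, fw$caches, array(1, dim = dim(fw$out)),
                     want_tap_grads = TRUE)
  # predicted-foreground aggregation (the default)
  restrict <- (pyrexcam:::sigmoid(fw$out[, , 1]) >= 0.5) * 1
  bwr <- net_backward(m, fw$caches, array(restrict, dim = dim(fw$out)),
                      want_tap_grads = TRUE)
  for (tap in c("backbone", "psp_concat")) {
    ctx <- cam_context(fw$taps[[tap]], bw$tap_grads[[tap]])
    manual <- cam_map(ctx, cam_weights(ctx), out_size = dim(img),
                      tap_point = tap)
    auto <- grad_cam(m, img, tap, restrict_to_prediction = FALSE)
    expect_equal(auto$values, manual$values)
    expect_equal(auto$raw_max, manual$raw_max)
    if (sum(restrict) > 0) {
      ctxr <- cam_context(fw$taps[[tap]], bwr$tap_grads[[tap]])
      manualr <- cam_map(ctxr, cam_weights(ctxr), out_size = dim(img),
                         tap_point = tap)
      autor <- grad_cam(m, img, tap)
      expect_equal(autor$values, manualr$values)
    }
  }
  expect_error(grad_cam(m, img, "nonexistent"), "tap point")
})

test_that("stage CAMs fuse the backbone with exactly one stage's channels", {
  m <- tiny_pspnet(seed = 18)
  img <- generate_phantom(tiny_spec(seed = 6))$image
  cams <- lapply(m$pyramid$scales, function(s) stage_cam(m, img, s))
  expect_length(cams, 4)
  for (cm in cams) expect_true(all(cm$values >= 0 & cm$values <= 1))
  # channel bookkeeping: backbone channels + union of stage channels
  # reproduce the psp_concat channel set exactly
  chmap <- m$psp_channel_map
  united <- sort(unique(c(chmap$backbone,
                          unlist(chmap[paste0("stage_", m$pyramid$scales)]))))
  fw <- net_forward(m, img)
  expect_identical(united, seq_len(dim(fw$taps$psp_concat)[3]))
  expect_error(stage_cam(m, img, 5), "configured scales")
})

test_that("a scale-1 stage contributes a spatially constant map before fusion", {
  m <- tiny_pspnet(seed = 21)
  img <- generate_phantom(tiny_spec(seed = 9))$image
  fw <- net_forward(m, img)
  bw <- net_backward(m, fw$caches, array(1, dim = dim(fw$out)),
                     want_tap_grads = TRUE)
  ch <- m$psp_channel_map$stage_1
  acts <- fw$taps$psp_concat[, , ch, drop = FALSE]
  grds <- bw$tap_grads$psp_concat[, , ch, drop = FALSE]
  ctx <- cam_context(acts, grds)
  cm <- cam_map(ctx, cam_weights(ctx))
  expect_lt(diff(range(cm$values)), 1e-9)
})

test_that("CAM invariants: non-negativity, zero-gradient nullity, scale homogeneity", {
  set.seed(7)
  acts <- array(rnorm(4 * 4 * 5), dim = c(4, 4, 5))
  grads <- array(rnorm(4 * 4 * 5), dim = c(4, 4, 5))
  ctx <- cam_context(acts, grads)
  cm <- cam_map(ctx, cam_weights(ctx))
  expect_true(all(cm$values >= 0))
  expect_true(max(cm$values) %in% c(0, 1))
  # zero gradients => zero map
  ctx0 <- cam_context(acts, grads * 0)
  cm0 <- cam_map(ctx0, cam_weights(ctx0))
  expect_equal(cm0$raw_max, 0)
  # scaling activations and gradients by c scales the raw map by c^2 and
  # leaves the normalized map unchanged
  cc <- 3.7
  ctx2 <- cam_context(acts * cc, grads * cc)
  cm2 <- cam_map(ctx2, cam_weights(ctx2))
  expect_equal(cm2$raw_max, cc^2 * cm$raw_max)
  expect_equal(cm2$values, cm$values)
})

test_that("attribution leaves a frozen model untouched", {
  m <- tiny_pspnet(seed = 55)
  img <- generate_phantom(tiny_spec(seed = 12))$image
  before <- param_checksum(m)
  invisible(backbone_cam(m, img))
  for (s in m$pyramid$scales) invisible(stage_cam(m, img, s))
  invisible(psp_cam(m, img))
  expect_identical(param_checksum(m), before)
})

test_that("psp_cam is deterministic and matches repeated evaluation", {
  m <- tiny_pspnet(seed = 2)
  img <- generate_phantom(tiny_spec(seed = 3))$image
  c1 <- psp_cam(m, img)
  c2 <- psp_cam(m, img)
  expect_identical(c1$values, c2$values)
})

test_that("overlays blend proportionally to the heat value", {
  img <- matrix(runif(16 * 16), 16, 16)
  zero <- structure(list(values = matrix(0, 16, 16), tap_point = "t",
                         raw_max = 0), class = "cam_map")
  ov <- cam_overlay(img, zero)
  for (ch in 1:3) expect_equal(ov[, , ch], img)
  ones <- structure(list(values = matrix(1, 16, 16), tap_point = "t",
                         raw_max = 1), class = "cam_map")
  ov1 <- cam_overlay(img, ones, alpha = 0.5)
  top <- pyrexcam:::jet_colors(1) / 255
  for (ch in 1:3)
    expect_equal(ov1[, , ch], 0.5 * img + 0.5 * top[ch])
  expect_error(cam_overlay(img, matrix(0, 4, 4)), "shape")
  # PNG round-trip (8-bit storage, so agreement to 1/255)
  p <- file.path(withr::local_tempdir(), "ov.png")
  png::writePNG(ov1, p)
  back <- png::readPNG(p)
  expect_lt(max(abs(back - ov1)), 1 / 255)
})
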