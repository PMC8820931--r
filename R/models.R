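#' Pyramid pooling configuration
#'
#' The pyramid module pools the backbone features onto each of the `scales`
#' output grids (adaptive average pooling, so scale `s` yields an `s x s`
#' summary), reduces each pooled map to `reduced_channels` with a 1x1
#' convolution, upsamples back bilinearly, multiplies by the stage weight,
#' and concatenates everything with the original features.
#'
#' @param scales strictly increasing positive integers, default `c(1,2,3,6)`.
#' @param reduced_channels channels per stage after the 1x1 reduction.
#' @param stage_weights positive scalar gain per stage, default all 1; the
#'   weighted variant studied here uses `c(1, 2, 2, 1)`.
#' @return an object of class `pyramid_config`.
#' @export
pyramid_config <- function(scales = c(1L, 2L, 3L, 6L),
                           reduced_channels = 16L,
                           stage_weights = NULL) {
  scales <- as.integer(scales)
  if (length(scales) == 0 || any(scales <= 0) ||
      any(diff(scales) <= 0))
    stop_invalid("scales", "must be strictly increasing positive integers")
  if (is.null(stage_weights)) stage_weights <- rep(1, length(scales))
  if (length(stage_weights) != length(scales) || any(stage_weights <= 0))
    stop_invalid("stage_weights",
                 "must be positive and match the number of scales")
  structure(list(scales = scales,
                 reduced_channels = as.integer(reduced_channels),
                 stage_weights = as.numeric(stage_weights)),
            class = "pyramid_config")
}

#' Training configuration
#'
#' Defaults follow the reference training regime: batch size 8, 10 epochs,
#' learning rate 1e-4, drop rate 0.01 (realized as dropout after the pyramid
#' concatenation), soft-dice loss, Adam.
#'
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param learning_rate Adam step size.
#' @param drop_rate dropout probability in [0, 1).
#' @param seed integer seed controlling shuffling and dropout.
#' @param loss loss identifier; `"soft-dice"` is the only built-in.
#' @param optimizer `"adam"` or `"sgd"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, epochs = 10L,
                         learning_rate = 1e-4, drop_rate = 0.01,
                         seed = 1L, loss = "soft-dice",
                         optimizer = c("adam", "sgd")) {
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0)
    stop_invalid("train_config", "batch_size, epochs, learning_rate must be positive")
  if (drop_rate < 0 || drop_rate >= 1)
    stop_invalid("drop_rate", "must lie in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, drop_rate = drop_rate,
                 seed = as.integer(seed), loss = loss,
                 optimizer = match.arg(optimizer)),
            class = "train_config")
}

backbone_widths <- function(backbone_depth) {
  switch(backbone_depth,
         small = c(stem = 16L, b1 = 32L, b2 = 32L, b3 = 64L),
         tiny  = c(stem = 8L,  b1 = 16L, b2 = 16L, b3 = 32L),
         stop_invalid("backbone_depth", "must be 'small' or 'tiny'"))
}

#' Build the pyramid scene parsing segmentation network
#'
#' A residual backbone (stem convolution plus three stride-2 residual blocks,
#' total downsampling x8), the pyramid pooling module, dropout, and a decoder
#' of three learned x2 deconvolutions followed by a 1x1 scoring convolution.
#' The forward pass on an `(h, w)` image yields per-pixel class scores at
#' input resolution.  Tap points exposed for attribution: `"backbone"`,
#' `"stage_<s>"` for every pyramid scale, and `"psp_concat"`.
#'
#' @param backbone_depth `"small"` (widths 16/32/32/64) or `"tiny"`.
#' @param pyramid a [pyramid_config()].
#' @param n_classes score channels (1 = binary whole-tumor head).
#' @param drop_rate dropout probability after the pyramid concatenation.
#' @param input_size expected square input size; used to validate that every
#'   pooling scale fits the `input_size / 8` backbone feature map.
#' @param seed seed for weight initialization.
#' @param norm apply per-image instance normalization after backbone and
#'   decoder convolutions; off by default (it slows early dice-loss
#'   convergence by suppressing global score shifts).
#' @return an object of classes `pspnet` and `pyrex_net`.
#' @export
build_pspnet <- function(backbone_depth = "small",
                         pyramid = pyramid_config(),
                         n_classes = 1L, drop_rate = 0.01,
                         input_size = 64L, seed = 1L, norm = FALSE) {
  wd <- backbone_widths(backbone_depth)
  feat <- input_size %/% 8L
  if (max(pyramid$scales) > feat)
    stop(sprintf(
      "configuration error: pooling scale %d exceeds the %dx%d backbone feature map (input %d, downsampling x8)",
      max(pyramid$scales), feat, feat, input_size), call. = FALSE)
  cb <- unname(wd["b3"])
  concat_c <- cb + length(pyramid$scales) * pyramid$reduced_channels
  layers <- list(
    layer_conv("stem", 1L, wd["stem"], norm = norm),
    layer_resblock("rb1", wd["stem"], wd["b1"], stride = 2L, norm = norm),
    layer_resblock("rb2", wd["b1"], wd["b2"], stride = 2L, norm = norm),
    layer_resblock("rb3", wd["b2"], wd["b3"], stride = 2L, norm = norm),
    layer_psp("psp", cb, pyramid),
    layer_dropout("drop", drop_rate),
    layer_deconv("dec1", concat_c, 64L, norm = norm),
    layer_deconv("dec2", 64L, 32L, norm = norm),
    layer_deconv("dec3", 32L, 32L, norm = norm),
    layer_conv("head", 32L, as.integer(n_classes), k = 1L, pad = 0L,
               relu = FALSE)
  )
  taps <- c(backbone = 4L, psp_concat = 5L)
  model <- build_seq_net(layers, taps, seed = seed, class = "pspnet")
  model$pyramid <- pyramid
  model$backbone_channels <- cb
  model$backbone_depth <- backbone_depth
  model$n_classes <- as.integer(n_classes)
  model$drop_rate <- drop_rate
  model$input_size <- as.integer(input_size)
  ch <- list(backbone = seq_len(cb))
  off <- cb
  for (s in pyramid$scales) {
    ch[[paste0("stage_", s)]] <- off + seq_len(pyramid$reduced_channels)
    off <- off + pyramid$reduced_channels
  }
  model$psp_channel_map <- ch
  model
}

#' Build the UNet baseline
#'
#' A standard encoder-decoder with skip connections: one convolution per
#' encoder level with 2x average-pool downsampling, a bottleneck, and
#' deconvolution upsampling with skip concatenation.  Decoder tap points
#' `conv_1` (bottleneck, coarsest) through `conv_<depth>` (full resolution)
#' are exposed for attribution.
#'
#' @param depth number of resolution levels (>= 2); depth 4 on a 64x64 input
#'   gives taps at resolutions 8, 16, 32, 64.
#' @param n_classes score channels.
#' @param base_width channels at the finest level (doubled per level, capped
#'   at 64).
#' @param seed seed for weight initialization.
#' @param norm apply per-image instance normalization after encoder/decoder
#'   convolutions (off by default, matching [build_pspnet()]).
#' @return an object of classes `unet` and `pyrex_net`.
#' @export
build_unet <- function(depth = 4L, n_classes = 1L, base_width = 8L,
                       seed = 1L, norm = FALSE) {
  depth <- as.integer(depth)
  if (depth < 2) stop_invalid("depth", "must be >= 2")
  w <- pmin(base_width * 2^(seq_len(depth) - 1L), 64L)
  layers <- list()
  cin <- 1L
  for (i in seq_len(depth - 1L)) {
    layers[[paste0("enc", i)]] <- layer_conv(paste0("enc", i), cin, w[i],
                                             norm = norm)
    cin <- w[i]
  }
  layers[["bott"]] <- layer_conv("bott", w[depth - 1L], w[depth],
                                 norm = norm)
  for (i in rev(seq_len(depth - 1L))) {
    layers[[paste0("up", i)]] <-
      layer_deconv(paste0("up", i), if (i == depth - 1L) w[depth] else w[i + 1L],
                   w[i], norm = norm)
    layers[[paste0("dec", i)]] <-
      layer_conv(paste0("dec", i), 2L * w[i], w[i], norm = norm)
  }
  layers[["head"]] <- layer_conv("head", w[1L], as.integer(n_classes),
                                 k = 1L, pad = 0L, relu = FALSE)
  params <- list()
  with_seed(seed, {
    for (l in layers) params <- c(params, init_layer_params(l))
  })
  structure(list(arch = "unet", depth = depth, widths = w, layers = layers,
                 params = params, n_classes = as.integer(n_classes),
                 taps = paste0("conv_", seq_len(depth))),
            class = c("unet", "pyrex_net"))
}

unet_forward <- function(model, x, training = FALSE) {
  d <- model$depth
  caches <- list(); taps <- list(); skips <- list()
  for (i in seq_len(d - 1L)) {
    r <- layer_forward(model$layers[[paste0("enc", i)]], model$params, x,
                       training)
    caches[[paste0("enc", i)]] <- r$cache
    skips[[i]] <- r$out
    p <- pool_half_fw(r$out)
    caches[[paste0("pool", i)]] <- p$cache
    x <- p$out
  }
  r <- layer_forward(model$layers[["bott"]], model$params, x, training)
  caches[["bott"]] <- r$cache
  x <- r$out
  taps[["conv_1"]] <- x
  for (i in rev(seq_len(d - 1L))) {
    u <- layer_forward(model$layers[[paste0("up", i)]], model$params, x,
                       training)
    caches[[paste0("up", i)]] <- u$cache
    cat_in <- array(0, dim = c(dim(u$out)[1], dim(u$out)[2],
                               dim(u$out)[3] + dim(skips[[i]])[3]))
    cat_in[, , seq_len(dim(u$out)[3])] <- u$out
    cat_in[, , dim(u$out)[3] + seq_len(dim(skips[[i]])[3])] <- skips[[i]]
    caches[[paste0("cat", i)]] <- c(dim(u$out)[3], dim(skips[[i]])[3])
    r <- layer_forward(model$layers[[paste0("dec", i)]], model$params,
                       cat_in, training)
    caches[[paste0("dec", i)]] <- r$cache
    x <- r$out
    taps[[paste0("conv_", d - i + 1L)]] <- x
  }
  r <- layer_forward(model$layers[["head"]], model$params, x, training)
  caches[["head"]] <- r$cache
  list(out = r$out, caches = caches, taps = taps)
}

unet_backward <- function(model, caches, gout, want_tap_grads = FALSE) {
  d <- model$depth
  grads <- list(); tap_grads <- list()
  add_grads <- function(grads, new) {
    for (nm in names(new))
      grads[[nm]] <- if (is.null(grads[[nm]])) new[[nm]]
                     else grads[[nm]] + new[[nm]]
    grads
  }
  r <- layer_backward(model$layers[["head"]], model$params, caches[["head"]],
                      gout)
  grads <- add_grads(grads, r$grads)
  g <- r$gx
  gskip <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    if (want_tap_grads) tap_grads[[paste0("conv_", d - i + 1L)]] <- g
    r <- layer_backward(model$layers[[paste0("dec", i)]], model$params,
                        caches[[paste0("dec", i)]], g)
    grads <- add_grads(grads, r$grads)
    nu <- caches[[paste0("cat", i)]][1]
    ns <- caches[[paste0("cat", i)]][2]
    gu <- array(r$gx[, , seq_len(nu)], dim = c(dim(r$gx)[1], dim(r$gx)[2], nu))
    gskip[[i]] <- array(r$gx[, , nu + seq_len(ns)],
                        dim = c(dim(r$gx)[1], dim(r$gx)[2], ns))
    r <- layer_backward(model$layers[[paste0("up", i)]], model$params,
                        caches[[paste0("up", i)]], gu)
    grads <- add_grads(grads, r$grads)
    g <- r$gx
  }
  if (want_tap_grads) tap_grads[["conv_1"]] <- g
  r <- layer_backward(model$layers[["bott"]], model$params, caches[["bott"]],
                      g)
  grads <- add_grads(grads, r$grads)
  g <- r$gx
  for (i in rev(seq_len(d - 1L))) {
    g <- adapt_avgpool_bw_cpp(g, caches[[paste0("pool", i)]]$h,
                              caches[[paste0("pool", i)]]$w)
    g <- g + gskip[[i]]
    r <- layer_backward(model$layers[[paste0("enc", i)]], model$params,
                        caches[[paste0("enc", i)]], g)
    grads <- add_grads(grads, r$grads)
    g <- r$gx
  }
  list(grads = grads, gx = g, tap_grads = tap_grads)
}

#' Forward pass of a network
#'
#' Runs the model on a 2D image (or `(H, W, C)` array), returning the score
#' map together with the activations at every tap point.
#'
#' @param model a `pyrex_net`.
#' @param x image matrix or tensor.
#' @param training logical; enables dropout.
#' @return list with `out` (score tensor at input resolution), `caches`
#'   (per-layer state for [net_backward()]), and `taps` (named activations).
#' @export
net_forward <- function(model, x, training = FALSE) {
  x <- as_tensor(x)
  if (identical(model$arch, "unet")) unet_forward(model, x, training)
  else seq_forward(model, x, training)
}

#' Backward pass of a network
#'
#' Backpropagates a gradient at the score map through the whole network.
#'
#' @param model a `pyrex_net`.
#' @param caches cache list returned by [net_forward()].
#' @param gout gradient w.r.t. the score tensor.
#' @param want_tap_grads also record gradients at every tap point.
#' @return list with `grads` (flat named parameter gradients), `gx` (gradient
#'   at the input), and `tap_grads`.
#' @export
net_backward <- function(model, caches, gout, want_tap_grads = FALSE) {
  if (identical(model$arch, "unet"))
    unet_backward(model, caches, gout, want_tap_grads)
  else seq_backward(model, caches, gout, want_tap_grads)
}

#' Pyramid module forward pass on explicit features
#'
#' Applies the model's pyramid pooling module to a feature tensor and
#' returns the full bundle: the input features, each stage's upsampled and
#' weighted map, and the concatenation.
#'
#' @param model a `pspnet`.
#' @param features `(h, w, C)` feature tensor with `C` equal to the backbone
#'   width.
#' @return list of class `feature_bundle` with `backbone_features`,
#'   `stage_features` (named per scale), and `concatenated`.
#' @export
psp_forward <- function(model, features) {
  stopifnot(inherits(model, "pspnet"))
  features <- as_tensor(features)
  psp_layer <- model$layers[[model$taps[["psp_concat"]]]]
  r <- psp_fw(psp_layer, model$params, features)
  stages <- r$cache$stage_raw
  names(stages) <- paste0("stage_", model$pyramid$scales)
  structure(list(backbone_features = features, stage_features = stages,
                 concatenated = r$out),
            class = "feature_bundle")
}

# ---- training --------------------------------------------------------------

soft_dice_loss <- function(logits, mask, smooth = 1) {
  p <- sigmoid(logits)
  sp <- sum(p); sg <- sum(mask); inter <- sum(p * mask)
  denom <- sp + sg + smooth
  dice <- (2 * inter + smooth) / denom
  # d(loss)/dp then chain through the sigmoid
  dd_dp <- (2 * mask * denom - (2 * inter + smooth)) / denom^2
  glogits <- -dd_dp * p * (1 - p)
  list(loss = 1 - dice, glogits = glogits)
}

adam_state_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a segmentation network
#'
#' Minimizes the soft dice loss `1 - (2 sum(p g) + 1) / (sum(p) + sum(g) + 1)`
#' on the sigmoid probability map with Adam (or plain SGD).  Shuffling and
#' dropout are driven by `cfg$seed`, so a fixed seed reproduces the loss
#' history bit for bit in single-threaded runs.
#'
#' @param model a `pyrex_net`.
#' @param samples non-empty list of [slice_sample()]s.
#' @param cfg a [train_config()].
#' @param val_samples optional held-out samples; mean dice is recorded per
#'   epoch.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained) and `history` (data frame with epoch,
#'   mean training loss, and validation dice when available).
#' @export
train_model <- function(model, samples, cfg = train_config(),
                        val_samples = NULL, verbose = FALSE) {
  if (length(samples) == 0)
    stop_invalid("samples", "training set is empty")
  dims <- unique(vapply(samples, function(s) paste(dim(s$image),
                                                   collapse = "x"),
                        character(1)))
  if (length(dims) != 1)
    stop_invalid("samples", "inconsistent slice shapes")
  n <- length(samples)
  params <- model$params
  state <- adam_state_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dice = numeric(0))
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = cfg$batch_size)) {
        batch <- idx[start:min(start + cfg$batch_size - 1, n)]
        bgrads <- NULL
        bloss <- 0
        model$params <- params
        for (i in batch) {
          fw <- net_forward(model, samples[[i]]$image, training = TRUE)
          sl <- soft_dice_loss(fw$out[, , 1], samples[[i]]$mask)
          if (!is.finite(sl$loss))
            stop(sprintf(
              "training aborted: non-finite loss at epoch %d (sample %d)",
              epoch, i), call. = FALSE)
          bloss <- bloss + sl$loss
          gout <- array(sl$glogits, dim = dim(fw$out))
          bw <- net_backward(model, fw$caches, gout)
          if (is.null(bgrads)) bgrads <- bw$grads
          else for (nm in names(bw$grads))
            bgrads[[nm]] <- bgrads[[nm]] + bw$grads[[nm]]
        }
        nb <- length(batch)
        for (nm in names(bgrads)) bgrads[[nm]] <- bgrads[[nm]] / nb
        if (identical(cfg$optimizer, "adam")) {
          st <- adam_step(params, bgrads, state, cfg$learning_rate)
          params <- st$params; state <- st$state
        } else {
          for (nm in names(bgrads))
            params[[nm]] <- params[[nm]] - cfg$learning_rate * bgrads[[nm]]
        }
        losses <- c(losses, bloss / nb)
      }
      model$params <- params
      vd <- NA_real_
      if (!is.null(val_samples))
        vd <- evaluate_split(model, val_samples)$mean_dice
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(losses),
                                  val_dice = vd))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val_dice %s", epoch,
                        mean(losses),
                        ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  })
  model$params <- params
  list(model = model, history = history)
}

#' Predict a segmentation for one slice
#'
#' @param object a trained `pyrex_net`.
#' @param image normalized image matrix in [0, 1].
#' @param threshold probability cut for the binary mask.
#' @param ... unused.
#' @return list with `prob` (probability matrix in [0, 1]) and `mask`
#'   (binary matrix, `prob >= threshold`).
#' @export
predict.pyrex_net <- function(object, image, threshold = 0.5, ...) {
  fw <- net_forward(object, image, training = FALSE)
  prob <- sigmoid(fw$out[, , 1])
  list(prob = prob, mask = (prob >= threshold) * 1)
}

#' Checksum of all model parameters
#'
#' Order-sensitive numeric digest of every parameter array; used to assert
#' that attribution leaves a frozen checkpoint untouched.
#'
#' @param model a `pyrex_net`.
#' @return named list of per-parameter digests.
#' @export
param_checksum <- function(model) {
  lapply(model$params, function(p) {
    v <- as.numeric(p)
    c(n = length(v), sum = sum(v), sumsq = sum(v * v),
      wsum = sum(v * seq_along(v)))
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS of the model plus a JSON sidecar echoing the
#' architecture and pyramid configuration for provenance.
#'
#' @param model a `pyrex_net`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model` invisibly returns the paths written; `load_model`
#'   returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  cfg <- list(arch = model$arch %||% class(model)[1],
              pyramid = if (!is.null(model$pyramid)) unclass(model$pyramid),
              n_classes = model$n_classes,
              backbone_depth = model$backbone_depth,
              depth = model$depth)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], side,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
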