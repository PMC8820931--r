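# Minimal CNN layer framework.
#
# Tensors are R arrays with dim (H, W, C).  A model holds a flat named list
# of parameters (`model$params`); layers reference parameters by id so the
# optimizer, checksums and serialization all operate on one flat list.
# Forward passes return per-layer caches; backward passes consume them and
# emit flat named gradient lists plus, on request, gradients at named tap
# points (the hooks Grad-CAM needs).

as_tensor <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer constructors ----------------------------------------------------

layer_conv <- function(id, cin, cout, k = 3L, stride = 1L, pad = NULL,
                       relu = TRUE, init = "he", gain = 1, norm = FALSE) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(type = "conv", id = id, cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), relu = relu,
       init = init, gain = gain, norm = norm)
}

layer_deconv <- function(id, cin, cout, k = 4L, stride = 2L, pad = 1L,
                         relu = TRUE, norm = FALSE) {
  list(type = "deconv", id = id, cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), relu = relu,
       norm = norm)
}

layer_resblock <- function(id, cin, cout, stride = 1L, norm = FALSE) {
  # residual unit y = F(x, {W_i}) + W_s x; the projection W_s is learned
  # exactly when channels or resolution change, identity otherwise
  list(type = "resblock", id = id, cin = cin, cout = cout,
       stride = as.integer(stride), norm = norm,
       uses_projection = (cin != cout || stride != 1L))
}

layer_psp <- function(id, cin, pyramid) {
  list(type = "psp", id = id, cin = cin, pyramid = pyramid)
}

layer_dropout <- function(id, p) {
  list(type = "dropout", id = id, p = p)
}

layer_pool_half <- function(id) {
  list(type = "pool_half", id = id)
}

# ---- parameter initialization ----------------------------------------------

he_mat <- function(nrow, ncol, fan_in, gain = 1) {
  matrix(rnorm(nrow * ncol, sd = gain * sqrt(2 / fan_in)), nrow, ncol)
}

init_layer_params <- function(layer) {
  p <- list()
  pre <- layer$id
  if (layer$type == "conv") {
    fan_in <- layer$cin * layer$k^2
    W <- if (identical(layer$init, "zero"))
      matrix(0, layer$cout, fan_in)
    else he_mat(layer$cout, fan_in, fan_in, layer$gain)
    p[[paste0(pre, ".W")]] <- W
    p[[paste0(pre, ".b")]] <- numeric(layer$cout)
    if (isTRUE(layer$norm)) {
      p[[paste0(pre, ".g")]] <- rep(1, layer$cout)
      p[[paste0(pre, ".beta")]] <- numeric(layer$cout)
    }
  } else if (layer$type == "deconv") {
    fan_in <- layer$cin * layer$k^2
    p[[paste0(pre, ".W")]] <- he_mat(layer$cin, layer$cout * layer$k^2,
                                     fan_in)
    p[[paste0(pre, ".b")]] <- numeric(layer$cout)
    if (isTRUE(layer$norm)) {
      p[[paste0(pre, ".g")]] <- rep(1, layer$cout)
      p[[paste0(pre, ".beta")]] <- numeric(layer$cout)
    }
  } else if (layer$type == "resblock") {
    for (sub in resblock_sublayers(layer))
      p <- c(p, init_layer_params(sub))
  } else if (layer$type == "psp") {
    r <- layer$pyramid$reduced_channels
    for (s in layer$pyramid$scales) {
      f <- layer$cin
      p[[sprintf("%s.reduce%d.W", pre, s)]] <- he_mat(r, f, f)
      p[[sprintf("%s.reduce%d.b", pre, s)]] <- numeric(r)
    }
  }
  p
}

# ---- instance normalization -------------------------------------------------
# per-image, per-channel standardization with learned scale/shift; the
# deterministic small-batch counterpart of the batch normalization used in
# the reference architectures

inorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  sd <- sqrt(pmax(v, 0) + eps)
  xhat <- (xm - rep(mu, each = hw)) / rep(sd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  list(out = array(y, dim = d), xhat = xhat, sd = sd)
}

inorm_bw <- function(gy, cache, gamma) {
  d <- dim(gy); hw <- d[1] * d[2]
  gym <- matrix(gy, hw, d[3])
  xhat <- cache$xhat
  gbeta <- colSums(gym)
  ggamma <- colSums(gym * xhat)
  gxhat <- gym * rep(gamma, each = hw)
  s1 <- colSums(gxhat) / hw
  s2 <- colSums(gxhat * xhat) / hw
  gx <- (gxhat - rep(s1, each = hw) - xhat * rep(s2, each = hw)) /
    rep(cache$sd, each = hw)
  list(gx = array(gx, dim = d), gbeta = gbeta, ggamma = ggamma)
}

# ---- primitive forward / backward ------------------------------------------

conv_fw <- function(layer, params, x) {
  W <- params[[paste0(layer$id, ".W")]]
  b <- params[[paste0(layer$id, ".b")]]
  lin <- conv2d_fw_cpp(x, W, b, layer$k, layer$k, layer$stride, layer$pad)
  norm_cache <- NULL
  pre <- lin
  if (isTRUE(layer$norm)) {
    nf <- inorm_fw(lin, params[[paste0(layer$id, ".g")]],
                   params[[paste0(layer$id, ".beta")]])
    pre <- nf$out
    norm_cache <- nf[c("xhat", "sd")]
  }
  out <- if (layer$relu) relu(pre) else pre
  list(out = out, cache = list(x = x, pre = if (layer$relu) pre else NULL,
                               norm = norm_cache))
}

conv_bw <- function(layer, params, cache, gout) {
  if (layer$relu) gout <- gout * (cache$pre > 0)
  g <- list()
  if (isTRUE(layer$norm)) {
    nb <- inorm_bw(gout, cache$norm, params[[paste0(layer$id, ".g")]])
    gout <- nb$gx
    g[[paste0(layer$id, ".g")]] <- nb$ggamma
    g[[paste0(layer$id, ".beta")]] <- nb$gbeta
  }
  W <- params[[paste0(layer$id, ".W")]]
  r <- conv2d_bw_cpp(cache$x, W, gout, layer$k, layer$k,
                     layer$stride, layer$pad)
  g[[paste0(layer$id, ".W")]] <- r$gW
  g[[paste0(layer$id, ".b")]] <- as.numeric(r$gb)
  list(gx = r$gx, grads = g)
}

deconv_fw <- function(layer, params, x) {
  W <- params[[paste0(layer$id, ".W")]]
  b <- params[[paste0(layer$id, ".b")]]
  lin <- convt2d_fw_cpp(x, W, b, layer$k, layer$k, layer$stride, layer$pad)
  norm_cache <- NULL
  pre <- lin
  if (isTRUE(layer$norm)) {
    nf <- inorm_fw(lin, params[[paste0(layer$id, ".g")]],
                   params[[paste0(layer$id, ".beta")]])
    pre <- nf$out
    norm_cache <- nf[c("xhat", "sd")]
  }
  out <- if (layer$relu) relu(pre) else pre
  list(out = out, cache = list(x = x, pre = if (layer$relu) pre else NULL,
                               norm = norm_cache))
}

deconv_bw <- function(layer, params, cache, gout) {
  if (layer$relu) gout <- gout * (cache$pre > 0)
  g <- list()
  if (isTRUE(layer$norm)) {
    nb <- inorm_bw(gout, cache$norm, params[[paste0(layer$id, ".g")]])
    gout <- nb$gx
    g[[paste0(layer$id, ".g")]] <- nb$ggamma
    g[[paste0(layer$id, ".beta")]] <- nb$gbeta
  }
  W <- params[[paste0(layer$id, ".W")]]
  r <- convt2d_bw_cpp(cache$x, W, gout, layer$k, layer$k,
                      layer$stride, layer$pad)
  g[[paste0(layer$id, ".W")]] <- r$gW
  g[[paste0(layer$id, ".b")]] <- as.numeric(r$gb)
  list(gx = r$gx, grads = g)
}

resblock_sublayers <- function(layer) {
  id <- layer$id
  subs <- list(
    layer_conv(paste0(id, ".conv1"), layer$cin, layer$cout,
               stride = layer$stride, relu = TRUE, norm = layer$norm),
    layer_conv(paste0(id, ".conv2"), layer$cout, layer$cout, relu = FALSE,
               norm = layer$norm))
  if (layer$uses_projection)
    subs <- c(subs, list(
      layer_conv(paste0(id, ".proj"), layer$cin, layer$cout, k = 1L,
                 stride = layer$stride, pad = 0L, relu = FALSE,
                 norm = layer$norm)))
  subs
}

resblock_fw <- function(layer, params, x) {
  subs <- resblock_sublayers(layer)
  f1 <- conv_fw(subs[[1]], params, x)
  f2 <- conv_fw(subs[[2]], params, f1$out)
  if (layer$uses_projection) {
    fp <- conv_fw(subs[[3]], params, x)
    shortcut <- fp$out
  } else {
    fp <- NULL
    shortcut <- x
  }
  pre <- f2$out + shortcut
  list(out = relu(pre),
       cache = list(x = x, c1 = f1$cache, c2 = f2$cache,
                    cp = if (!is.null(fp)) fp$cache else NULL, pre = pre))
}

resblock_bw <- function(layer, params, cache, gout) {
  subs <- resblock_sublayers(layer)
  g <- gout * (cache$pre > 0)
  b2 <- conv_bw(subs[[2]], params, cache$c2, g)
  b1 <- conv_bw(subs[[1]], params, cache$c1, b2$gx)
  grads <- c(b2$grads, b1$grads)
  if (layer$uses_projection) {
    bp <- conv_bw(subs[[3]], params, cache$cp, g)
    grads <- c(grads, bp$grads)
    gx <- b1$gx + bp$gx
  } else {
    gx <- b1$gx + g
  }
  list(gx = gx, grads = grads)
}

# pyramid pooling: adaptive average pool to s x s, 1x1 reduction conv (ReLU),
# bilinear upsample back, scalar stage weight, concatenate with the input
psp_fw <- function(layer, params, x) {
  py <- layer$pyramid
  h <- dim(x)[1]; w <- dim(x)[2]
  if (min(h, w) < max(py$scales))
    stop(sprintf(
      "configuration error: pooling scale %d exceeds feature map size %dx%d",
      max(py$scales), h, w), call. = FALSE)
  stages <- list(); caches <- list()
  for (i in seq_along(py$scales)) {
    s <- py$scales[i]
    pooled <- adapt_avgpool_fw_cpp(x, s, s)
    cl <- layer_conv(sprintf("%s.reduce%d", layer$id, s), layer$cin,
                     py$reduced_channels, k = 1L, pad = 0L, relu = TRUE)
    red <- conv_fw(cl, params, pooled)
    up <- bilinear_fw_cpp(red$out, h, w)
    stages[[i]] <- py$stage_weights[i] * up
    caches[[i]] <- list(red = red$cache, s = s)
  }
  out <- array(0, dim = c(h, w, layer$cin +
                            length(py$scales) * py$reduced_channels))
  out[, , seq_len(layer$cin)] <- x
  off <- layer$cin
  for (i in seq_along(stages)) {
    out[, , off + seq_len(py$reduced_channels)] <- stages[[i]]
    off <- off + py$reduced_channels
  }
  list(out = out,
       cache = list(x = x, stages = caches, h = h, w = w, stage_raw = stages))
}

psp_bw <- function(layer, params, cache, gout) {
  py <- layer$pyramid
  gx <- array(gout[, , seq_len(layer$cin)],
              dim = c(cache$h, cache$w, layer$cin))
  grads <- list()
  off <- layer$cin
  for (i in seq_along(py$scales)) {
    s <- py$scales[i]
    gstage <- array(gout[, , off + seq_len(py$reduced_channels)],
                    dim = c(cache$h, cache$w, py$reduced_channels))
    off <- off + py$reduced_channels
    gup <- py$stage_weights[i] * gstage
    gred <- bilinear_bw_cpp(gup, s, s)
    cl <- layer_conv(sprintf("%s.reduce%d", layer$id, s), layer$cin,
                     py$reduced_channels, k = 1L, pad = 0L, relu = TRUE)
    br <- conv_bw(cl, params, cache$stages[[i]]$red, gred)
    grads <- c(grads, br$grads)
    gx <- gx + adapt_avgpool_bw_cpp(br$gx, cache$h, cache$w)
  }
  list(gx = gx, grads = grads)
}

dropout_fw <- function(layer, x, training) {
  if (!training || layer$p <= 0)
    return(list(out = x, cache = list(mask = NULL)))
  mask <- array((runif(length(x)) >= layer$p) / (1 - layer$p), dim = dim(x))
  list(out = x * mask, cache = list(mask = mask))
}

pool_half_fw <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  list(out = adapt_avgpool_fw_cpp(x, h %/% 2L, w %/% 2L),
       cache = list(h = h, w = w))
}

layer_forward <- function(layer, params, x, training = FALSE) {
  switch(layer$type,
    conv = conv_fw(layer, params, x),
    deconv = deconv_fw(layer, params, x),
    resblock = resblock_fw(layer, params, x),
    psp = psp_fw(layer, params, x),
    dropout = dropout_fw(layer, x, training),
    pool_half = pool_half_fw(x),
    stop(sprintf("unknown layer type %s", layer$type)))
}

layer_backward <- function(layer, params, cache, gout) {
  switch(layer$type,
    conv = conv_bw(layer, params, cache, gout),
    deconv = deconv_bw(layer, params, cache, gout),
    resblock = resblock_bw(layer, params, cache, gout),
    psp = psp_bw(layer, params, cache, gout),
    dropout = {
      gx <- if (is.null(cache$mask)) gout else gout * cache$mask
      list(gx = gx, grads = list())
    },
    pool_half = list(gx = adapt_avgpool_bw_cpp(gout, cache$h, cache$w),
                     grads = list()),
    stop(sprintf("unknown layer type %s", layer$type)))
}

# ---- sequential networks ---------------------------------------------------

# taps: named integer vector mapping tap name -> layer index whose OUTPUT is
# the tapped activation.
build_seq_net <- function(layers, taps = integer(0), seed = 1L,
                          class = "seq_net") {
  params <- list()
  with_seed(seed, {
    for (l in layers) params <- c(params, init_layer_params(l))
  })
  structure(list(arch = "seq", layers = layers, params = params, taps = taps),
            class = c(class, "pyrex_net"))
}

seq_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  taps <- list()
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], model$params, x, training)
    caches[[i]] <- r$cache
    x <- r$out
    hit <- names(model$taps)[model$taps == i]
    for (nm in hit) taps[[nm]] <- x
  }
  list(out = x, caches = caches, taps = taps)
}

seq_backward <- function(model, caches, gout, want_tap_grads = FALSE) {
  grads <- list()
  tap_grads <- list()
  g <- gout
  for (i in rev(seq_along(model$layers))) {
    if (want_tap_grads) {
      hit <- names(model$taps)[model$taps == i]
      for (nm in hit) tap_grads[[nm]] <- g
    }
    r <- layer_backward(model$layers[[i]], model$params, caches[[i]], g)
    for (nm in names(r$grads)) {
      grads[[nm]] <- if (is.null(grads[[nm]])) r$grads[[nm]]
                     else grads[[nm]] + r$grads[[nm]]
    }
    g <- r$gx
  }
  list(grads = grads, gx = g, tap_grads = tap_grads)
}

# run the tail of a sequential net starting from the activations at a tap
seq_forward_from <- function(model, tap, acts, training = FALSE) {
  idx <- model$taps[[tap]]
  if (is.null(idx)) stop(sprintf("unknown tap %s", tap), call. = FALSE)
  x <- acts
  if (idx < length(model$layers)) {
    for (i in (idx + 1):length(model$layers)) {
      x <- layer_forward(model$layers[[i]], model$params, x, training)$out
    }
  }
  x
}
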