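# Shared fixtures: everything is generated in code under fixed seeds.

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_size = 64L, n_lesions = 1L,
                   lesion_radius_range = c(5, 10), noise_sigma = 0.02,
                   seed = 101L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

tiny_samples <- function(n = 4, seed = 5, ...) {
  generate_dataset(n, tiny_spec(...), seed = seed)$samples
}

# small randomly initialized pyramid net shared across tests (untrained)
tiny_pspnet <- function(seed = 9, ...) {
  build_pspnet(backbone_depth = "tiny", input_size = 64L, seed = seed, ...)
}

# a 2-conv sequential toy network with taps after each layer; used for
# finite-difference attribution oracles
toy_net <- function(seed = 3, cin = 1L, c1 = 4L, c2 = 3L) {
  layers <- list(
    pyrexcam:::layer_conv("l1", cin, c1, k = 3L),
    pyrexcam:::layer_conv("l2", c1, c2, k = 3L),
    pyrexcam:::layer_conv("out", c2, 1L, k = 1L, pad = 0L, relu = FALSE)
  )
  pyrexcam:::build_seq_net(layers, taps = c(tap1 = 1L, tap2 = 2L),
                           seed = seed)
}

# central finite-difference estimate of d(sum of scores)/d(activations at a
# tap), averaged per channel -- the independent oracle for cam_weights
fd_alpha <- function(model, tap, acts, h = 1e-4) {
  K <- dim(acts)[3]
  Z <- dim(acts)[1] * dim(acts)[2]
  alpha <- numeric(K)
  for (k in seq_len(K)) {
    g <- 0
    for (i in seq_len(dim(acts)[1])) for (j in seq_len(dim(acts)[2])) {
      ap <- acts; ap[i, j, k] <- ap[i, j, k] + h
      am <- acts; am[i, j, k] <- am[i, j, k] - h
      yp <- sum(pyrexcam:::seq_forward_from(model, tap, ap))
      ym <- sum(pyrexcam:::seq_forward_from(model, tap, am))
      g <- g + (yp - ym) / (2 * h)
    }
    alpha[k] <- g / Z
  }
  alpha
}
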