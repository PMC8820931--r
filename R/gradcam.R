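#' Scalar target score for dense prediction
#'
#' The class score backpropagated by Grad-CAM.  For a segmentation head the
#' class score is taken as the spatial sum of the target-class score map
#' (optionally restricted to a mask of pixels, e.g. the predicted
#' foreground), which reduces the dense output to the scalar quantity whose
#' gradients drive the attribution.
#'
#' @param score_map matrix or `(h, w, C)` score tensor.
#' @param class_index channel to aggregate (1 for the binary head).
#' @param restrict optional binary matrix; only pixels with value 1
#'   contribute.
#' @return scalar score.
#' @export
target_score <- function(score_map, class_index = 1L, restrict = NULL) {
  score_map <- as_tensor(score_map)
  if (class_index < 1 || class_index > dim(score_map)[3])
    stop_invalid("class_index", sprintf("must be in 1..%d", dim(score_map)[3]))
  m <- score_map[, , class_index]
  if (!is.null(restrict)) {
    if (!identical(dim(restrict), dim(m)))
      stop_invalid("restrict", "shape must match the score map")
    m <- m * restrict
  }
  sum(m)
}

#' Bundle activations and gradients captured at a tap point
#'
#' @param activations `(h, w, K)` activations at the tap.
#' @param gradients gradient of the target score w.r.t. the activations,
#'   same shape.
#' @param class_index target class index.
#' @return object of class `cam_context`; `Z = h * w` is the pooling
#'   normalizer.
#' @export
cam_context <- function(activations, gradients, class_index = 1L) {
  activations <- as_tensor(activations)
  gradients <- as_tensor(gradients)
  if (!identical(dim(activations), dim(gradients)))
    stop_invalid("gradients", "shape must match activations")
  structure(list(activations = activations, gradients = gradients,
                 class_index = as.integer(class_index),
                 Z = dim(activations)[1] * dim(activations)[2]),
            class = "cam_context")
}

#' Per-channel attribution weights
#'
#' Global average pooling of the backpropagated gradients: the weight of
#' channel `k` is the spatial mean of the gradient of the class score with
#' respect to that channel's activation map.
#'
#' @param ctx a [cam_context()].
#' @return numeric vector of length `K`.
#' @export
cam_weights <- function(ctx) {
  stopifnot(inherits(ctx, "cam_context"))
  apply(ctx$gradients, 3, sum) / ctx$Z
}

#' Class-discriminative localization map
#'
#' The ReLU-rectified weighted channel sum of the activations, bilinearly
#' upsampled to the requested resolution and min-max normalized to [0, 1].
#' An identically zero raw map (all channel contributions negative or zero)
#' is passed through unscaled with `raw_max = 0`.
#'
#' @param ctx a [cam_context()].
#' @param alpha per-channel weights, typically [cam_weights()] output.
#' @param out_size `c(h, w)` output resolution; defaults to the tap
#'   resolution.
#' @param tap_point label stored on the result.
#' @return object of class `cam_map` with fields `values` (matrix in
#'   [0, 1]), `tap_point`, and `raw_max`.
#' @export
cam_map <- function(ctx, alpha, out_size = NULL, tap_point = "unknown") {
  stopifnot(inherits(ctx, "cam_context"))
  K <- dim(ctx$activations)[3]
  if (length(alpha) != K)
    stop_invalid("alpha", sprintf("length must equal %d channels", K))
  raw <- matrix(0, dim(ctx$activations)[1], dim(ctx$activations)[2])
  for (k in seq_len(K)) raw <- raw + alpha[k] * ctx$activations[, , k]
  raw <- pmax(raw, 0)
  if (!is.null(out_size) &&
      !identical(as.integer(out_size), as.integer(dim(raw)))) {
    raw <- bilinear_fw_cpp(array(raw, dim = c(dim(raw), 1L)),
                           out_size[1], out_size[2])[, , 1]
  }
  raw_max <- max(raw)
  values <- if (raw_max > 0) raw / raw_max else raw
  structure(list(values = values, tap_point = tap_point, raw_max = raw_max),
            class = "cam_map")
}

# shared driver: forward, spatial-sum score, one backward pass, then weights
# and map from the requested tap
grad_cam_impl <- function(model, image, tap, class_index = 1L,
                          restrict_to_prediction = FALSE, threshold = 0.5) {
  fw <- net_forward(model, image, training = FALSE)
  restrict <- NULL
  if (restrict_to_prediction) {
    restrict <- (sigmoid(fw$out[, , class_index]) >= threshold) * 1
    # empty prediction: fall back to the full spatial sum
    if (sum(restrict) == 0) restrict <- NULL
  }
  gout <- array(0, dim = dim(fw$out))
  gout[, , class_index] <- if (is.null(restrict)) 1 else restrict
  bw <- net_backward(model, fw$caches, gout, want_tap_grads = TRUE)
  size <- dim(as_tensor(image))[1:2]
  is_stage <- grepl("^stage_", tap)
  base_tap <- if (is_stage) "psp_concat" else tap
  acts <- fw$taps[[base_tap]]
  grds <- bw$tap_grads[[base_tap]]
  if (is.null(acts))
    stop(sprintf("model has no tap point '%s' (available: %s)", tap,
                 paste(names(fw$taps), collapse = ", ")), call. = FALSE)
  if (is_stage) {
    chmap <- model$psp_channel_map
    if (is.null(chmap[[tap]]))
      stop(sprintf("unknown scale tap '%s'; configured stages: %s", tap,
                   paste(grep("^stage_", names(chmap), value = TRUE),
                         collapse = ", ")), call. = FALSE)
    # fuse the backbone channels with only this stage's channels: the
    # attribution sees the single-scale fusion, not the full concatenation
    keep <- c(chmap$backbone, chmap[[tap]])
    acts <- acts[, , keep, drop = FALSE]
    grds <- grds[, , keep, drop = FALSE]
  }
  ctx <- cam_context(acts, grds, class_index)
  cam_map(ctx, cam_weights(ctx), out_size = size, tap_point = tap)
}

#' Grad-CAM at a named tap point
#'
#' By default the class score is aggregated over the predicted foreground
#' pixels (`restrict_to_prediction = TRUE`), which yields localization maps
#' that cover the segmented structure; with `FALSE` the score is the plain
#' sum over all pixels, which on a confident model concentrates the
#' normalized map onto a few feature cells.
#'
#' @param model a `pyrex_net` with tap points (see [build_pspnet()] and
#'   [build_unet()]).
#' @param image normalized input image matrix.
#' @param tap tap name: `"backbone"`, `"stage_<s>"`, `"psp_concat"`, or
#'   `"conv_<i>"` for the UNet.
#' @param class_index target class channel.
#' @param restrict_to_prediction aggregate the class score over predicted
#'   foreground pixels only instead of all pixels.
#' @param threshold probability cut used when `restrict_to_prediction`.
#' @return a [cam_map()].
#' @export
grad_cam <- function(model, image, tap, class_index = 1L,
                     restrict_to_prediction = TRUE, threshold = 0.5) {
  grad_cam_impl(model, image, tap, class_index, restrict_to_prediction,
                threshold)
}

#' Grad-CAM at the backbone features
#'
#' @inheritParams grad_cam
#' @return a [cam_map()] with `tap_point = "backbone"`.
#' @export
backbone_cam <- function(model, image, ...) grad_cam(model, image, "backbone", ...)

#' Grad-CAM at one pyramid stage
#'
#' The stage's upsampled, weighted features are fused (concatenated) with
#' the backbone features and the fused map is attributed; the remaining
#' stages are excluded, so each scale is visualized in isolation exactly as
#' it enters the concatenation.
#'
#' @inheritParams grad_cam
#' @param scale one of the model's configured pyramid scales.
#' @return a [cam_map()] with `tap_point = "stage_<scale>"`.
#' @export
stage_cam <- function(model, image, scale, ...) {
  if (!scale %in% model$pyramid$scales)
    stop(sprintf("unknown scale %s; configured scales: %s", scale,
                 paste(model$pyramid$scales, collapse = ", ")),
         call. = FALSE)
  grad_cam(model, image, paste0("stage_", scale), ...)
}

#' Grad-CAM at the concatenated pyramid context features
#'
#' @inheritParams grad_cam
#' @return a [cam_map()] with `tap_point = "psp_concat"`; this is the
#'   "PSP-Features" heat map.
#' @export
psp_cam <- function(model, image, ...) grad_cam(model, image, "psp_concat", ...)

jet_colors <- grDevices::colorRamp(
  c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
    "#FFFF00", "#FF7F00", "#FF0000", "#7F0000"))

#' Render a heat-map overlay
#'
#' Alpha-blends the colormapped heat map over the grayscale image; the
#' blend weight at a pixel is `alpha * cam`, so zero-heat pixels show the
#' plain image and full-heat pixels show the top colormap color at the
#' configured alpha.
#'
#' @param image grayscale matrix in [0, 1].
#' @param cam a [cam_map()] (or plain matrix in [0, 1]) of the same shape.
#' @param alpha maximum blend weight in [0, 1].
#' @return `(h, w, 3)` RGB array in [0, 1].
#' @export
cam_overlay <- function(image, cam, alpha = 0.5) {
  v <- if (inherits(cam, "cam_map")) cam$values else cam
  if (!identical(dim(v), dim(image)))
    stop_invalid("cam", "shape must match the image")
  cols <- jet_colors(as.vector(v)) / 255
  out <- array(0, dim = c(dim(image), 3L))
  w <- alpha * as.vector(v)
  for (ch in 1:3)
    out[, , ch] <- matrix((1 - w) * as.vector(image) + w * cols[, ch],
                          nrow(image), ncol(image))
  out
}

#' Write an overlay (or plain CAM) as PNG
#'
#' @param rgb `(h, w, 3)` array in [0, 1] (e.g. [cam_overlay()] output).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
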