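#' Smoothed dice coefficient
#'
#' `dice = (2 |X intersect Y| + smooth) / (|X| + |Y| + smooth)` with
#' cardinalities as pixel counts and `smooth = 1` by default, so two empty
#' masks score 1 and the value always lies in (0, 1].  With `soft = TRUE`
#' the second argument may be a probability map in [0, 1] (the training
#' loss uses this variant).
#'
#' @param x binary ground-truth matrix.
#' @param y binary segmentation matrix (or probability map when `soft`).
#' @param smooth additive smoothing constant.
#' @param soft allow `y` in [0, 1].
#' @return scalar in (0, 1].
#' @export
dice_coefficient <- function(x, y, smooth = 1, soft = FALSE) {
  if (!identical(dim(x), dim(y)))
    stop_invalid("x/y", "shapes must match")
  if (!all(x %in% c(0, 1)))
    stop_invalid("x", "must be binary")
  if (!soft && !all(y %in% c(0, 1)))
    stop_invalid("y", "must be binary (use soft = TRUE for probabilities)")
  (2 * sum(x * y) + smooth) / (sum(x) + sum(y) + smooth)
}

#' Binarize a heat map at a threshold
#'
#' Pixels with value `>= threshold` become foreground.  On a min-max
#' normalized CAM, lowering the threshold can only enlarge the foreground.
#'
#' @param cam a [cam_map()] or a numeric matrix in [0, 1].
#' @param threshold value in [0, 1].
#' @return binary matrix.
#' @export
binarize_cam <- function(cam, threshold) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop_invalid("threshold", "must lie in [0, 1]")
  v <- if (inherits(cam, "cam_map")) cam$values else cam
  (v >= threshold) * 1
}

#' PSNR between two binary images
#'
#' With peak value 1 on \{0, 1\} images the mean squared error equals the
#' mismatch fraction, so `PSNR = -10 log10(mismatch fraction)` in dB.
#' Identical images return `Inf` (infinite similarity sentinel);
#' complementary images return 0.
#'
#' @param a,b binary matrices of equal shape.
#' @return PSNR in dB.
#' @export
psnr_binary <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_invalid("a/b", "shapes must match")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop_invalid("a/b", "must be binary")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}

#' Mean PSNR of binarized heat maps against output and ground truth
#'
#' For every threshold, each heat map is binarized and compared (PSNR)
#' with the corresponding predicted mask and with the ground-truth mask;
#' the two PSNR series are averaged over images.  Infinite sentinel values
#' (exact matches) are excluded from the means and counted.
#'
#' @param cams list of [cam_map()]s (or matrices in [0, 1]).
#' @param outputs list of binary predicted masks, same length.
#' @param gts list of binary ground-truth masks, same length.
#' @param thresholds increasing thresholds; default is the 0.05-0.45 grid
#'   in steps of 0.05.
#' @return data frame of class `psnr_curve_table` with columns `threshold`,
#'   `mean_psnr_vs_output`, `mean_psnr_vs_gt`; attributes `n_images`,
#'   `n_excluded` (per reference), and `per_image` (the full PSNR arrays).
#' @export
psnr_curve <- function(cams, outputs, gts,
                       thresholds = seq(0.05, 0.45, by = 0.05)) {
  if (length(cams) != length(outputs) || length(cams) != length(gts))
    stop_invalid("cams/outputs/gts", "lengths must match")
  if (any(diff(thresholds) <= 0))
    stop_invalid("thresholds", "must be strictly increasing")
  n <- length(cams)
  po <- matrix(NA_real_, n, length(thresholds))
  pg <- matrix(NA_real_, n, length(thresholds))
  for (i in seq_len(n)) {
    for (j in seq_along(thresholds)) {
      b <- binarize_cam(cams[[i]], thresholds[j])
      po[i, j] <- psnr_binary(b, outputs[[i]])
      pg[i, j] <- psnr_binary(b, gts[[i]])
    }
  }
  finite_mean <- function(x) mean(x[is.finite(x)])
  tab <- data.frame(
    threshold = thresholds,
    mean_psnr_vs_output = apply(po, 2, finite_mean),
    mean_psnr_vs_gt = apply(pg, 2, finite_mean))
  n_exc <- c(output = sum(!is.finite(po)), gt = sum(!is.finite(pg)))
  if (any(n_exc > 0))
    message(sprintf(
      "psnr_curve: excluded %d infinite PSNR values vs output, %d vs GT",
      n_exc["output"], n_exc["gt"]))
  structure(tab, class = c("psnr_curve_table", "data.frame"),
            n_images = n, n_excluded = n_exc,
            per_image = list(output = po, gt = pg))
}

#' Evaluate a model on a sample split
#'
#' @param model a trained `pyrex_net`.
#' @param samples non-empty list of [slice_sample()]s.
#' @param threshold probability cut for the predicted mask.
#' @return list of class `metrics_record` with `mean_dice`, `per_sample`
#'   (data frame), `n`, and `threshold`.
#' @export
evaluate_split <- function(model, samples, threshold = 0.5) {
  if (length(samples) == 0)
    stop_invalid("samples", "evaluation split is empty")
  d <- vapply(samples, function(s) {
    pr <- predict(model, s$image, threshold = threshold)
    dice_coefficient(s$mask, pr$mask)
  }, numeric(1))
  structure(list(
    mean_dice = mean(d),
    per_sample = data.frame(index = seq_along(samples) - 1L, dice = d),
    n = length(samples), threshold = threshold),
    class = "metrics_record")
}
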