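#' Plan for a seeded phantom-scale experiment
#'
#' Bundles everything an experiment harness needs: the model variants to
#' compare, the training regime, the phantom generator settings, sample
#' counts, the master seed, and the output directory.  Every harness below
#' is a pure function of its plan, so rerunning a plan reproduces its
#' metrics exactly.
#'
#' @param name experiment name (used in file names).
#' @param variants list of [pyramid_config()]s (model variants).
#' @param train_cfg a [train_config()].
#' @param phantom a [phantom_spec()] describing the data distribution.
#' @param n_train,n_eval training / evaluation sample counts.
#' @param seed master seed; training data, evaluation data, and weight
#'   initialization seeds are derived from it.
#' @param outputs_dir directory for galleries, CSV tables and summaries.
#' @param save_galleries write PNG galleries (disable for quick metric runs).
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(name, variants = list(pyramid_config()),
                            train_cfg = train_config(),
                            phantom = phantom_spec(),
                            n_train = 32L, n_eval = 8L, seed = 1L,
                            outputs_dir = tempfile("pyrexcam_"),
                            save_galleries = TRUE) {
  if (length(variants) < 1) stop_invalid("variants", "need at least one")
  structure(list(name = name, variants = variants, train_cfg = train_cfg,
                 phantom = phantom, n_train = as.integer(n_train),
                 n_eval = as.integer(n_eval), seed = as.integer(seed),
                 outputs_dir = outputs_dir,
                 save_galleries = isTRUE(save_galleries)),
            class = "experiment_plan")
}

# YAML echo of the plan (seeds included) written next to every harness's
# outputs so a result directory is self-describing
echo_plan <- function(plan) {
  dir.create(plan$outputs_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(name = plan$name,
              variants = lapply(plan$variants, unclass),
              train_cfg = unclass(plan$train_cfg),
              phantom = unclass(plan$phantom),
              n_train = plan$n_train, n_eval = plan$n_eval,
              seed = plan$seed)
  yaml::write_yaml(cfg, file.path(plan$outputs_dir,
                                  paste0(plan$name, "_config.yaml")))
  invisible(cfg)
}

plan_data <- function(plan, image_size = NULL) {
  spec <- plan$phantom
  if (!is.null(image_size)) spec$image_size <- as.integer(image_size)
  train <- generate_dataset(plan$n_train, spec,
                            seed = derive_sample_seed(plan$seed, 1L))
  eval <- generate_dataset(plan$n_eval, spec,
                           seed = derive_sample_seed(plan$seed, 2L))
  list(train = train$samples, eval = eval$samples,
       image_size = spec$image_size)
}

# input side length a pyramid variant needs given x8 backbone downsampling;
# widened (and recorded) when a pooling scale outgrows the feature map
required_input_size <- function(pyramid, base_size) {
  need <- 8L * max(pyramid$scales)
  max(as.integer(base_size), need)
}

train_variant <- function(plan, pyramid, data, variant_seed = 0L) {
  model <- build_pspnet(pyramid = pyramid,
                        drop_rate = plan$train_cfg$drop_rate,
                        input_size = data$image_size,
                        seed = derive_sample_seed(plan$seed, 100L + variant_seed))
  tr <- train_model(model, data$train, plan$train_cfg,
                    val_samples = data$eval)
  tr
}

variant_gallery <- function(model, samples, dir, taps = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pre <- file.path(dir, sprintf("sample%03d", i))
    pr <- predict(model, s$image)
    png::writePNG(s$image, paste0(pre, "_input.png"))
    png::writePNG(s$mask, paste0(pre, "_gt.png"))
    png::writePNG(pr$mask, paste0(pre, "_output.png"))
    files <- c(files, paste0(pre, c("_input.png", "_gt.png", "_output.png")))
    if (taps) {
      cams <- c(list(backbone = backbone_cam(model, s$image)),
                stats::setNames(
                  lapply(model$pyramid$scales,
                         function(sc) stage_cam(model, s$image, sc)),
                  paste0("stage_", model$pyramid$scales)),
                list(psp = psp_cam(model, s$image)))
      for (nm in names(cams)) {
        p <- paste0(pre, "_cam_", nm, ".png")
        write_overlay_png(cam_overlay(s$image, cams[[nm]]), p)
        files <- c(files, p)
      }
    }
  }
  files
}

# mean pairwise mean-absolute-difference between the normalized stage CAMs
# of one image; low values mean the scales attend to the same regions
stage_consistency <- function(cams) {
  k <- length(cams)
  if (k < 2) return(NA_real_)
  acc <- 0; np <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    acc <- acc + mean(abs(cams[[i]]$values - cams[[j]]$values))
    np <- np + 1
  }
  acc / np
}

#' Visualize the pyramid structure on held-out phantoms
#'
#' Trains the first variant of the plan and emits, per evaluation image,
#' the full interpretation panel: input, ground truth, model output, the
#' backbone CAM, one CAM per pyramid stage, and the concatenated-features
#' CAM.  Also records per-sample dice and the mean pairwise difference
#' between stage CAMs.
#'
#' @param plan an [experiment_plan()].
#' @return list with `mean_dice`, `per_sample` dice, `stage_difference`
#'   (mean pairwise stage-CAM difference per sample), `gallery` (paths),
#'   `history`, and `model`.
#' @export
run_pyramid_validity <- function(plan) {
  echo_plan(plan)
  data <- plan_data(plan, required_input_size(plan$variants[[1]],
                                              plan$phantom$image_size))
  tr <- train_variant(plan, plan$variants[[1]], data)
  metrics <- evaluate_split(tr$model, data$eval)
  sd <- vapply(data$eval, function(s) {
    cams <- lapply(tr$model$pyramid$scales,
                   function(sc) stage_cam(tr$model, s$image, sc))
    stage_consistency(cams)
  }, numeric(1))
  gallery <- character(0)
  dir.create(plan$outputs_dir, showWarnings = FALSE, recursive = TRUE)
  if (plan$save_galleries)
    gallery <- variant_gallery(tr$model, data$eval,
                               file.path(plan$outputs_dir, "validity"))
  df <- metrics$per_sample
  df$stage_difference <- sd
  write.csv(df, file.path(plan$outputs_dir, "validity_metrics.csv"),
            row.names = FALSE)
  list(mean_dice = metrics$mean_dice, per_sample = df,
       stage_difference = sd, gallery = gallery, history = tr$history,
       model = tr$model)
}

assert_same_except <- function(a, b, field) {
  fa <- unclass(a); fb <- unclass(b)
  fa[[field]] <- NULL; fb[[field]] <- NULL
  if (!identical(fa, fb))
    stop(sprintf("variants must differ only in %s", field), call. = FALSE)
  invisible(TRUE)
}

#' Compare uniform and weighted pyramid stage gains
#'
#' Trains two models under identical data and seeds that differ only in
#' their stage weights (canonically 1:1:1:1 versus 1:2:2:1, emphasizing the
#' 2x2 and 3x3 scales), and reports dice plus the binarized-CAM PSNR curve
#' for each.
#'
#' @param plan an [experiment_plan()] whose `variants` are exactly the two
#'   pyramid configurations (uniform first).
#' @return named list (`uniform`, `weighted`), each with `mean_dice`,
#'   `psnr_table`, `stage_weights`, `history`, and `model`.
#' @export
run_weighting_experiment <- function(plan) {
  echo_plan(plan)
  if (length(plan$variants) != 2)
    stop("weighting experiment needs exactly two variants", call. = FALSE)
  assert_same_except(plan$variants[[1]], plan$variants[[2]], "stage_weights")
  data <- plan_data(plan, required_input_size(plan$variants[[1]],
                                              plan$phantom$image_size))
  dir.create(plan$outputs_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  keys <- c("uniform", "weighted")
  for (v in 1:2) {
    tr <- train_variant(plan, plan$variants[[v]], data, variant_seed = 0L)
    metrics <- evaluate_split(tr$model, data$eval)
    cams <- lapply(data$eval, function(s) psp_cam(tr$model, s$image))
    outputs <- lapply(data$eval, function(s) predict(tr$model, s$image)$mask)
    gts <- lapply(data$eval, function(s) s$mask)
    curve <- psnr_curve(cams, outputs, gts)
    write.csv(curve,
              file.path(plan$outputs_dir,
                        sprintf("weighting_psnr_%s.csv", keys[v])),
              row.names = FALSE)
    if (plan$save_galleries)
      variant_gallery(tr$model, data$eval,
                      file.path(plan$outputs_dir, paste0("weighting_",
                                                         keys[v])))
    out[[keys[v]]] <- list(mean_dice = metrics$mean_dice,
                           psnr_table = curve,
                           stage_weights = plan$variants[[v]]$stage_weights,
                           history = tr$history, model = tr$model)
  }
  write.csv(data.frame(variant = keys,
                       mean_dice = c(out$uniform$mean_dice,
                                     out$weighted$mean_dice)),
            file.path(plan$outputs_dir, "weighting_dice.csv"),
            row.names = FALSE)
  out
}

#' Scale-count ablation of the pyramid module
#'
#' Trains one model per pyramid variant (canonically the four-scale set
#' \{1,2,3,6\}, the six-scale set \{1,2,3,6,8,12\}, and the two-scale set
#' \{2,3\}), holding every non-pyramid hyperparameter fixed.  Variants whose
#' largest scale outgrows the backbone feature map are trained at a widened
#' input size, and the widening is recorded.  Reports mean dice, the
#' concatenated channel count, and the stage-consistency score (mean
#' pairwise absolute difference between stage CAMs; lower = more redundant
#' scales).
#'
#' @param plan an [experiment_plan()] with one [pyramid_config()] per
#'   variant.
#' @return list of per-variant results plus a `summary` data frame
#'   (also written to `scale_ablation_metrics.csv`).
#' @export
run_scale_ablation <- function(plan) {
  echo_plan(plan)
  dir.create(plan$outputs_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  rows <- list()
  for (v in seq_along(plan$variants)) {
    py <- plan$variants[[v]]
    size <- required_input_size(py, plan$phantom$image_size)
    data <- plan_data(plan, size)
    tr <- train_variant(plan, py, data, variant_seed = v - 1L)
    metrics <- evaluate_split(tr$model, data$eval)
    cons <- mean(vapply(data$eval, function(s) {
      cams <- lapply(py$scales, function(sc) stage_cam(tr$model, s$image, sc))
      stage_consistency(cams)
    }, numeric(1)))
    vid <- paste(py$scales, collapse = "-")
    concat_c <- tr$model$backbone_channels +
      length(py$scales) * py$reduced_channels
    rows[[v]] <- data.frame(
      variant = vid, n_scales = length(py$scales),
      input_size = size, widened = size > plan$phantom$image_size,
      concat_channels = concat_c, mean_dice = metrics$mean_dice,
      stage_consistency = cons)
    if (plan$save_galleries)
      variant_gallery(tr$model, data$eval,
                      file.path(plan$outputs_dir, paste0("scales_", vid)))
    results[[vid]] <- list(variant_id = vid, mean_dice = metrics$mean_dice,
                           stage_consistency = cons,
                           concat_channels = concat_c,
                           input_size = size, history = tr$history,
                           model = tr$model)
  }
  summary <- do.call(rbind, rows)
  write.csv(summary, file.path(plan$outputs_dir,
                               "scale_ablation_metrics.csv"),
            row.names = FALSE)
  results$summary <- summary
  results
}

#' Compare the pyramid network with the UNet baseline
#'
#' Trains both models with identical data, seeds and training settings and
#' reports their dice side by side, plus per-decoder-level UNet CAMs and
#' per-stage pyramid CAMs for the evaluation images.
#'
#' @param plan an [experiment_plan()]; the first variant configures the
#'   pyramid model.
#' @param unet_depth UNet resolution levels.
#' @return list with `table` (rows UNet / PSPNet), `pspnet`, `unet`.
#' @export
run_unet_comparison <- function(plan, unet_depth = 4L) {
  echo_plan(plan)
  data <- plan_data(plan, required_input_size(plan$variants[[1]],
                                              plan$phantom$image_size))
  dir.create(plan$outputs_dir, showWarnings = FALSE, recursive = TRUE)
  tr_psp <- train_variant(plan, plan$variants[[1]], data)
  unet <- build_unet(depth = unet_depth,
                     seed = derive_sample_seed(plan$seed, 200L))
  tr_un <- train_model(unet, data$train, plan$train_cfg,
                       val_samples = data$eval)
  m_psp <- evaluate_split(tr_psp$model, data$eval)
  m_un <- evaluate_split(tr_un$model, data$eval)
  tab <- data.frame(model = c("UNet", "PSPNet"),
                    mean_dice = c(m_un$mean_dice, m_psp$mean_dice))
  write.csv(tab, file.path(plan$outputs_dir, "unet_comparison.csv"),
            row.names = FALSE)
  unet_gallery <- list()
  if (plan$save_galleries) {
    variant_gallery(tr_psp$model, data$eval,
                    file.path(plan$outputs_dir, "compare_pspnet"))
    dir <- file.path(plan$outputs_dir, "compare_unet")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(data$eval)) {
      s <- data$eval[[i]]
      for (tp in tr_un$model$taps) {
        cm <- grad_cam(tr_un$model, s$image, tp)
        p <- file.path(dir, sprintf("sample%03d_cam_%s.png", i, tp))
        write_overlay_png(cam_overlay(s$image, cm), p)
        unet_gallery[[length(unet_gallery) + 1L]] <- p
      }
    }
  }
  list(table = tab,
       pspnet = list(mean_dice = m_psp$mean_dice, model = tr_psp$model,
                     history = tr_psp$history),
       unet = list(mean_dice = m_un$mean_dice, model = tr_un$model,
                   history = tr_un$history,
                   gallery = unlist(unet_gallery)))
}

#' Write a Markdown report for experiment results
#'
#' Deterministic (no timestamps): rerunning on the same results reproduces
#' the report byte for byte.  Every number in the report is read back from
#' the CSV files the harnesses wrote.
#'
#' @param results named list of harness results (any subset of
#'   `validity`, `weighting`, `ablation`, `unet`).
#' @param out_dir directory containing the harness CSV outputs; the report
#'   is written there as `report.md`.
#' @return the report path, invisibly.
#' @export
write_report <- function(results, out_dir) {
  if (length(results) == 0) stop_invalid("results", "empty")
  lines <- c("# pyrexcam experiment report", "")
  fmt_tab <- function(df) {
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(vapply(df[i, ], function(x)
          if (is.numeric(x)) sprintf("%.4f", x) else as.character(x),
          character(1)), collapse = " | "), " |"), character(1)),
      "")
  }
  if (!is.null(results$validity)) {
    df <- read.csv(file.path(out_dir, "validity_metrics.csv"))
    lines <- c(lines, "## Pyramid structure visualization", "",
               fmt_tab(df))
  }
  if (!is.null(results$weighting)) {
    df <- read.csv(file.path(out_dir, "weighting_dice.csv"))
    lines <- c(lines, "## Stage weighting (uniform vs 1:2:2:1)", "",
               fmt_tab(df))
    for (k in c("uniform", "weighted")) {
      df <- read.csv(file.path(out_dir,
                               sprintf("weighting_psnr_%s.csv", k)))
      lines <- c(lines, sprintf("### Binarized-CAM PSNR curve (%s)", k), "",
                 fmt_tab(df))
    }
  }
  if (!is.null(results$ablation)) {
    df <- read.csv(file.path(out_dir, "scale_ablation_metrics.csv"))
    lines <- c(lines, "## Scale-count ablation", "", fmt_tab(df))
  }
  if (!is.null(results$unet)) {
    df <- read.csv(file.path(out_dir, "unet_comparison.csv"))
    lines <- c(lines, "## UNet baseline comparison", "", fmt_tab(df))
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
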