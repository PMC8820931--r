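# Harness tests run at reduced problem sizes (few phantoms, 1-2 epochs);
# they exercise structure and determinism, not segmentation quality.

quick_plan <- function(dir, variants = list(pyramid_config(reduced_channels = 4L)),
                       n_train = 6L, n_eval = 3L, epochs = 1L,
                       galleries = TRUE, seed = 31L) {
  experiment_plan("quick", variants = variants,
                  train_cfg = train_config(batch_size = 4L, epochs = epochs,
                                           learning_rate = 1e-3, seed = seed),
                  phantom = tiny_spec(),
                  n_train = n_train, n_eval = n_eval, seed = seed,
                  outputs_dir = dir, save_galleries = galleries)
}

test_that("the validity harness emits the full interpretation panel per image", {
  dir <- withr::local_tempdir()
  plan <- quick_plan(dir)
  res <- run_pyramid_validity(plan)
  # per sample: input, gt, output + backbone, 4 stage CAMs, psp CAM = 8
  n_scales <- length(plan$variants[[1]]$scales)
  expect_length(res$gallery, plan$n_eval * (3 + n_scales + 2))
  expect_true(all(file.exists(res$gallery)))
  expect_true(file.exists(file.path(dir, "validity_metrics.csv")))
  expect_true(res$mean_dice > 0 && res$mean_dice <= 1)
  # stage CAMs differ pairwise on at least some images (positive mean
  # pairwise difference)
  expect_true(any(res$stage_difference > 0))
})

test_that("the weighting harness trains uniform and 1:2:2:1 variants under one seed", {
  dir <- withr::local_tempdir()
  plan <- quick_plan(dir, variants = list(
    pyramid_config(reduced_channels = 4L),
    pyramid_config(reduced_channels = 4L, stage_weights = c(1, 2, 2, 1))),
    galleries = FALSE)
  res <- run_weighting_experiment(plan)
  expect_named(res, c("uniform", "weighted"))
  expect_equal(res$weighted$stage_weights, c(1, 2, 2, 1))
  expect_s3_class(res$uniform$psnr_table, "psnr_curve_table")
  expect_identical(nrow(res$uniform$psnr_table), 9L)
  expect_true(file.exists(file.path(dir, "weighting_dice.csv")))
  # variants may differ only in stage_weights
  bad <- quick_plan(dir, variants = list(
    pyramid_config(reduced_channels = 4L),
    pyramid_config(reduced_channels = 8L, stage_weights = c(1, 2, 2, 1))))
  expect_error(run_weighting_experiment(bad), "stage_weights")
  expect_error(run_weighting_experiment(quick_plan(dir)), "two variants")
})

test_that("identical weighting variants yield identical dice (determinism control)", {
  dir <- withr::local_tempdir()
  plan <- quick_plan(dir, variants = list(
    pyramid_config(reduced_channels = 4L),
    pyramid_config(reduced_channels = 4L)), galleries = FALSE)
  res <- run_weighting_experiment(plan)
  expect_identical(res$uniform$mean_dice, res$weighted$mean_dice)
})

test_that("the scale ablation covers the studied scale sets and records widening", {
  dir <- withr::local_tempdir()
  plan <- quick_plan(dir, variants = list(
    pyramid_config(scales = c(1, 2, 3, 6), reduced_channels = 4L),
    pyramid_config(scales = c(1, 2, 3, 6, 8, 12), reduced_channels = 4L),
    pyramid_config(scales = c(2, 3), reduced_channels = 4L)),
    n_train = 4L, n_eval = 2L, galleries = FALSE)
  res <- run_scale_ablation(plan)
  s <- res$summary
  expect_identical(nrow(s), 3L)
  expect_equal(s$n_scales, c(4L, 6L, 2L))
  # channel conservation per variant (small backbone: 64 channels)
  expect_equal(s$concat_channels, 64 + s$n_scales * 4)
  # the 12-scale variant cannot fit a 64-input backbone; it is widened to 96
  expect_identical(s$widened, c(FALSE, TRUE, FALSE))
  expect_identical(s$input_size[2], 96L)
  # stage-consistency scores recompute from the trained models
  v <- res[["1-2-3-6"]]
  expect_true(is.finite(v$stage_consistency))
})

test_that("scale 12 on a 64 input fails fast when widening is not applied", {
  expect_error(build_pspnet(pyramid = pyramid_config(scales = c(1, 2, 3, 6, 8, 12)),
                            input_size = 64L),
               "configuration error")
})

test_that("the UNet comparison reports both models in one table", {
  dir <- withr::local_tempdir()
  plan <- quick_plan(dir, galleries = TRUE, n_eval = 2L)
  res <- run_unet_comparison(plan, unet_depth = 3L)
  expect_identical(res$table$model, c("UNet", "PSPNet"))
  expect_true(all(res$table$mean_dice > 0 & res$table$mean_dice <= 1))
  # one CAM per decoder level per evaluation image
  expect_length(res$unet$gallery, 3L * plan$n_eval)
  expect_true(file.exists(file.path(dir, "unet_comparison.csv")))
})

test_that("reports are deterministic and re-derivable from the CSVs", {
  dir <- withr::local_tempdir()
  plan <- quick_plan(dir, galleries = FALSE, n_train = 4L, n_eval = 2L)
  res <- run_pyramid_validity(plan)
  p1 <- write_report(list(validity = res), dir)
  r1 <- readLines(p1)
  p2 <- write_report(list(validity = res), dir)
  expect_identical(readLines(p2), r1)
  csv <- read.csv(file.path(dir, "validity_metrics.csv"))
  expect_true(all(vapply(sprintf("%.4f", csv$dice), function(x)
    any(grepl(x, r1, fixed = TRUE)), logical(1))))
  expect_error(write_report(list(), dir), "empty")
})

test_that("rerunning an ablation plan reproduces its metric files exactly", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  vs <- list(pyramid_config(scales = c(2, 3), reduced_channels = 4L))
  r1 <- run_scale_ablation(quick_plan(dir1, variants = vs, n_train = 4L,
                                      n_eval = 2L, galleries = FALSE))
  r2 <- run_scale_ablation(quick_plan(dir2, variants = vs, n_train = 4L,
                                      n_eval = 2L, galleries = FALSE))
  expect_identical(readLines(file.path(dir1, "scale_ablation_metrics.csv")),
                   readLines(file.path(dir2, "scale_ablation_metrics.csv")))
})
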