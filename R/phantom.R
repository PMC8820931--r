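#' Specification for a synthetic MRI-like phantom slice
#'
#' Describes one 2D grayscale phantom: a dark background, a smooth elliptical
#' "brain" field, one or more bright circular lesions with a linearly decaying
#' halo, and additive Gaussian noise.  The defaults emulate the appearance of
#' a whole-tumor lesion on a Flair slice: a high-intensity blob with a diffuse
#' rim on a mid-intensity brain parenchyma.
#'
#' @param image_size side length of the square slice in pixels (>= 32).
#' @param n_lesions number of lesion disks (>= 0).
#' @param lesion_radius_range numeric pair `c(min, max)` of disk radii in
#'   pixels, `min <= max`, `max < image_size / 2`.
#' @param lesion_intensity lesion brightness relative to the image maximum,
#'   in (0, 1].
#' @param halo_width width in pixels of the linearly decaying rim around each
#'   lesion (0 disables the halo).
#' @param noise_sigma standard deviation of the per-pixel additive Gaussian
#'   noise (>= 0).
#' @param background_level base parenchyma intensity in [0, 1).
#' @param seed integer seed for the Mersenne-Twister stream used to draw the
#'   brain ellipse, lesion radii/centres, and noise.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(image_size = 64L,
                         n_lesions = 1L,
                         lesion_radius_range = c(5, 12),
                         lesion_intensity = 0.85,
                         halo_width = 3,
                         noise_sigma = 0.05,
                         background_level = 0.15,
                         seed = 1L) {
  spec <- list(
    image_size = as.integer(image_size),
    n_lesions = as.integer(n_lesions),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_intensity = as.numeric(lesion_intensity),
    halo_width = as.numeric(halo_width),
    noise_sigma = as.numeric(noise_sigma),
    background_level = as.numeric(background_level),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!is.finite(spec$image_size) || spec$image_size < 32)
    stop_invalid("image_size", "must be an integer >= 32")
  if (is.na(spec$n_lesions) || spec$n_lesions < 0)
    stop_invalid("n_lesions", "must be a non-negative integer")
  r <- spec$lesion_radius_range
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0)
    stop_invalid("lesion_radius_range", "must be positive with min <= max")
  if (r[2] >= spec$image_size / 2)
    stop_invalid("lesion_radius_range", "max radius must be < image_size / 2")
  if (!is.finite(spec$lesion_intensity) ||
      spec$lesion_intensity <= 0 || spec$lesion_intensity > 1)
    stop_invalid("lesion_intensity", "must lie in (0, 1]")
  if (!is.finite(spec$halo_width) || spec$halo_width < 0)
    stop_invalid("halo_width", "must be >= 0")
  if (!is.finite(spec$noise_sigma) || spec$noise_sigma < 0)
    stop_invalid("noise_sigma", "must be >= 0")
  if (!is.finite(spec$background_level) ||
      spec$background_level < 0 || spec$background_level >= 1)
    stop_invalid("background_level", "must lie in [0, 1)")
  invisible(spec)
}

#' Construct a 2D slice sample
#'
#' The unit of data flowing through the pipeline: one grayscale image in
#' [0, 1] with a binary target mask of the same shape plus provenance.
#'
#' @param image numeric matrix with values in [0, 1].
#' @param mask binary matrix (0/1) of the same shape.
#' @param case_id case identifier string.
#' @param slice_index non-negative integer slice index within the case.
#' @param modality one of `"T1"`, `"T2"`, `"Flair"`, `"T1ce"`, `"synthetic"`.
#' @param target segmentation target, one of `"WT"`, `"TC"`, `"ET"`.
#' @return an object of class `slice_sample`.
#' @export
slice_sample <- function(image, mask, case_id = "case", slice_index = 0L,
                         modality = "synthetic", target = "WT") {
  if (!is.matrix(image) || !is.matrix(mask) ||
      !identical(dim(image), dim(mask)))
    stop_invalid("image/mask", "must be matrices of identical shape")
  if (!all(mask %in% c(0, 1)))
    stop_invalid("mask", "values must be 0 or 1")
  modality <- match.arg(modality, c("T1", "T2", "Flair", "T1ce", "synthetic"))
  target <- match.arg(target, c("WT", "TC", "ET"))
  structure(
    list(image = image, mask = mask, case_id = case_id,
         slice_index = as.integer(slice_index), modality = modality,
         target = target),
    class = "slice_sample"
  )
}

# Deterministic per-sample seed derivation: a fixed odd multiplier keeps the
# derived streams well separated while staying inside 32-bit integer range.
derive_sample_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 2654435.0 + index * 97.0) %% 2147483647)
}

#' Generate one phantom slice
#'
#' Draws, in order: the brain ellipse geometry, then per lesion a radius
#' (uniform over `lesion_radius_range`) and a centre (uniform over the brain
#' ellipse eroded by the radius, so every disk lies fully inside the brain
#' and the image), then the pixel noise.  The mask is the union of the lesion
#' disks; halos are image-only.  The same seed therefore reproduces the image
#' and mask bit for bit, and enlarging the radius range (holding the seed)
#' can only grow the mask.
#'
#' @param spec a [phantom_spec()].
#' @return a [slice_sample()] with `modality = "synthetic"`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$image_size
  with_seed(spec$seed, {
    xs <- matrix(rep(seq_len(n), each = n), nrow = n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), nrow = n)  # row index
    cx <- n / 2 + runif(1, -0.03, 0.03) * n
    cy <- n / 2 + runif(1, -0.03, 0.03) * n
    a <- n * runif(1, 0.40, 0.45)  # semi-axis, x
    b <- n * runif(1, 0.36, 0.42)  # semi-axis, y
    inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

    # smooth parenchyma texture: coarse Gaussian field upsampled bilinearly
    coarse <- array(rnorm(8 * 8), dim = c(8, 8, 1))
    field <- bilinear_fw_cpp(coarse, n, n)[, , 1]
    field <- (field - min(field)) / max(max(field) - min(field), 1e-12)
    img <- matrix(0, n, n)
    img[inside] <- spec$background_level + 0.30 * field[inside]

    mask <- matrix(0, n, n)
    lesions <- list()
    if (spec$n_lesions > 0) {
      for (k in seq_len(spec$n_lesions)) {
        rad <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        # uniform draw over the unit disk, mapped into the eroded ellipse;
        # the draw does not depend on rad, so a larger radius range moves the
        # centre by at most (r2 - r1) and the disk grows monotonically
        ang <- runif(1, 0, 2 * pi)
        rho <- sqrt(runif(1))
        u <- rho * cos(ang)
        v <- rho * sin(ang)
        lx <- cx + u * max(a - rad - 1, 0)
        ly <- cy + v * max(b - rad - 1, 0)
        d <- sqrt((xs - lx)^2 + (ys - ly)^2)
        disk <- d <= rad
        mask[disk] <- 1
        lesions[[k]] <- c(x = lx, y = ly, radius = rad)
        img[disk] <- pmax(img[disk], spec$lesion_intensity)
        if (spec$halo_width > 0) {
          halo <- !disk & d <= rad + spec$halo_width
          fade <- spec$lesion_intensity *
            (1 - (d[halo] - rad) / spec$halo_width)
          img[halo] <- pmax(img[halo], fade)
        }
      }
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(n * n, sd = spec$noise_sigma), n, n)
    img <- pmin(pmax(img, 0), 1)
    s <- slice_sample(img, mask, case_id = sprintf("phantom_%08d", spec$seed),
                      slice_index = 0L, modality = "synthetic", target = "WT")
    # lesion geometry (continuous centre x/y in column/row pixel
    # coordinates, radius) kept as provenance
    s$lesions <- do.call(rbind, lesions)
    s
  })
}

#' Generate a reproducible phantom dataset
#'
#' Each sample gets its own seed derived from `seed` and the sample index;
#' the manifest records every per-sample seed so any single sample can be
#' regenerated in isolation with [generate_phantom()].
#'
#' @param n_samples number of slices (>= 1).
#' @param spec a [phantom_spec()]; its own `seed` field is ignored in favour
#'   of the derived per-sample seeds.
#' @param seed master integer seed.
#' @return list with elements `samples` (list of [slice_sample()]) and
#'   `manifest` (list with the master seed, the spec, and per-sample seeds).
#' @export
generate_dataset <- function(n_samples, spec, seed = 1L) {
  if (!is.finite(n_samples) || n_samples < 1)
    stop_invalid("n_samples", "must be >= 1")
  n_samples <- as.integer(n_samples)
  seeds <- vapply(seq_len(n_samples), function(i) derive_sample_seed(seed, i),
                  integer(1))
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sp <- spec
    sp$seed <- seeds[i]
    s <- generate_phantom(sp)
    s$slice_index <- i - 1L
    samples[[i]] <- s
  }
  manifest <- list(
    generator = "pyrexcam phantom v1 (Mersenne-Twister)",
    master_seed = as.integer(seed),
    n_samples = n_samples,
    sample_seeds = seeds,
    spec = unclass(spec)
  )
  list(samples = samples, manifest = manifest)
}

#' Write phantom samples as a BraTS-layout NIfTI fixture case
#'
#' Stacks the slices along the first axis into `(n_slices, H, W)` volumes and
#' writes one image volume per modality present in `samples` plus one label
#' volume (`<case>_seg.nii.gz`) in which lesion pixels carry `label_value`.
#' The layout mirrors a BraTS case directory so [read_volume()] can read it
#' back.
#'
#' @param samples non-empty list of [slice_sample()]s with identical shapes.
#' @param out_dir output directory (created if missing).
#' @param case_id case name used as the filename prefix.
#' @param label_value positive integer written at mask-foreground pixels
#'   (default 2, the edema label, a member of the whole-tumor set).
#' @return named character vector of the files written.
#' @export
write_fixture_volume <- function(samples, out_dir, case_id = "case0001",
                                 label_value = 2L) {
  if (length(samples) == 0)
    stop_invalid("samples", "must be a non-empty list")
  dims <- lapply(samples, function(s) dim(s$image))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all samples must share the same slice shape", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- dims[[1]][1]; w <- dims[[1]][2]; n <- length(samples)
  paths <- character(0)
  for (mod in unique(vapply(samples, `[[`, character(1), "modality"))) {
    vol <- array(0, dim = c(n, h, w))
    for (i in seq_len(n)) vol[i, , ] <- samples[[i]]$image
    p <- file.path(out_dir, sprintf("%s_%s.nii.gz", case_id, mod))
    RNifti::writeNifti(vol, p)
    paths[mod] <- p
  }
  seg <- array(0L, dim = c(n, h, w))
  for (i in seq_len(n)) seg[i, , ] <- as.integer(samples[[i]]$mask) * label_value
  p <- file.path(out_dir, sprintf("%s_seg.nii.gz", case_id))
  RNifti::writeNifti(seg, p)
  paths["seg"] <- p
  paths
}

#' Export a slice (and optionally its mask) as PNG
#'
#' @param sample a [slice_sample()].
#' @param path output PNG path for the image.
#' @param mask_path optional output path for the binary mask.
#' @return invisibly, the paths written.
#' @export
write_slice_png <- function(sample, path, mask_path = NULL) {
  png::writePNG(pmin(pmax(sample$image, 0), 1), path)
  if (!is.null(mask_path)) png::writePNG(sample$mask, mask_path)
  invisible(c(path, mask_path))
}
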