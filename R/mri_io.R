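#' Read a BraTS-style NIfTI volume
#'
#' Axes are ordered `(slice, height, width)`; the slice axis is the first
#' axis, so a standard BraTS case reads as `(155, 240, 240)`.  Modality is
#' inferred from the filename convention `<case>_<modality>.nii(.gz)`; a
#' `_seg` suffix marks a label volume.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return an object of class `volume3d`: list with `data` (3D array),
#'   `modality`, `case_id`, `is_label`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  data <- tryCatch(as.array(RNifti::readNifti(path)),
                   error = function(e)
                     stop(sprintf("cannot read NIfTI file %s: %s",
                                  path, conditionMessage(e)), call. = FALSE))
  if (length(dim(data)) != 3)
    stop(sprintf("%s: expected 3 axes (slice, height, width), got %d",
                 path, length(dim(data))), call. = FALSE)
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  modality <- parts[length(parts)]
  case_id <- paste(parts[-length(parts)], collapse = "_")
  if (case_id == "") case_id <- base
  is_label <- identical(modality, "seg")
  structure(list(data = data, modality = modality, case_id = case_id,
                 is_label = is_label),
            class = "volume3d")
}

#' Cut a 3D volume into 2D slices
#'
#' @param vol a `volume3d` (or a bare 3D array); slicing is along the first
#'   axis, so a `(155, 240, 240)` volume yields 155 matrices of 240 x 240.
#' @return list of matrices, one per slice.
#' @export
slice_volume <- function(vol) {
  data <- if (inherits(vol, "volume3d")) vol$data else vol
  if (length(dim(data)) != 3)
    stop("expected 3 axes", call. = FALSE)
  lapply(seq_len(dim(data)[1]), function(i) data[i, , ])
}

#' Stack 2D slices back into a 3D array
#'
#' Inverse of [slice_volume()]: `stack_slices(slice_volume(v))` equals
#' `v$data`.
#'
#' @param slices list of equally shaped matrices.
#' @return 3D array `(n_slices, height, width)`.
#' @export
stack_slices <- function(slices) {
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  out <- array(0, dim = c(length(slices), h, w))
  for (i in seq_along(slices)) out[i, , ] <- slices[[i]]
  out
}

#' Segmentation target specification
#'
#' Encodes which integer labels form a target region and which modality is
#' used to segment it.  The presets follow the BraTS convention for the
#' three nested targets: whole tumor WT = \{1, 2, 4\} on Flair, tumor core
#' TC = \{1, 4\} on Flair, enhancing tumor ET = \{4\} on T1ce.
#'
#' @param target `"WT"`, `"TC"` or `"ET"`.
#' @param label_values optional non-empty set of positive integer labels
#'   overriding the preset.
#' @param modality optional modality override (`"Flair"` or `"T1ce"`).
#' @return an object of class `target_spec`.
#' @export
target_spec <- function(target = c("WT", "TC", "ET"),
                        label_values = NULL, modality = NULL) {
  target <- match.arg(target)
  presets <- list(WT = list(values = c(1L, 2L, 4L), modality = "Flair"),
                  TC = list(values = c(1L, 4L), modality = "Flair"),
                  ET = list(values = 4L, modality = "T1ce"))
  values <- if (is.null(label_values)) presets[[target]]$values
            else as.integer(label_values)
  if (length(values) == 0 || any(values <= 0))
    stop_invalid("label_values", "must be a non-empty set of positive integers")
  modality <- if (is.null(modality)) presets[[target]]$modality
              else match.arg(modality, c("Flair", "T1ce"))
  structure(list(target = target, label_values = values, modality = modality),
            class = "target_spec")
}

#' Derive a binary target mask from an integer label slice
#'
#' A pixel is foreground exactly when its label belongs to
#' `spec$label_values`.  Labels outside the known BraTS set
#' \{0, 1, 2, 4\} trigger a warning and count as background.
#'
#' @param label_slice integer-valued matrix.
#' @param spec a [target_spec()].
#' @return binary matrix of the same shape.
#' @export
extract_target_mask <- function(label_slice, spec) {
  if (!is.matrix(label_slice))
    stop_invalid("label_slice", "must be a matrix")
  vals <- unique(as.vector(label_slice))
  if (any(vals != round(vals)))
    stop_invalid("label_slice", "must be integer-valued")
  known <- c(0L, 1L, 2L, 4L)
  unknown <- setdiff(as.integer(vals), union(known, spec$label_values))
  if (length(unknown) > 0)
    warning(sprintf("unknown label values treated as background: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  mask <- matrix(as.numeric(label_slice %in% spec$label_values),
                 nrow(label_slice), ncol(label_slice))
  mask
}

#' Min-max normalize a slice to [0, 1]
#'
#' Per-slice min-max scaling; a constant slice maps to all zeros.
#'
#' @param image numeric matrix with finite values.
#' @return matrix with values in [0, 1].
#' @export
normalize_slice <- function(image) {
  if (!all(is.finite(image)))
    stop_invalid("image", "contains NaN or infinite values")
  lo <- min(image); hi <- max(image)
  if (hi - lo <= 0) return(matrix(0, nrow(image), ncol(image)))
  (image - lo) / (hi - lo)
}

#' Load a BraTS-layout case as slice samples for one target
#'
#' Reads the modality volume named by `spec$modality` (falling back to a
#' `synthetic` volume when present) and the `_seg` label volume, slices
#' both, extracts the binary target mask per slice, and min-max normalizes
#' each image slice.
#'
#' @param case_dir directory containing `<case>_<modality>.nii.gz` files.
#' @param spec a [target_spec()].
#' @param drop_empty drop slices with empty target masks (default keeps
#'   them).
#' @return list of [slice_sample()]s.
#' @export
load_case_slices <- function(case_dir, spec = target_spec("WT"),
                             drop_empty = FALSE) {
  files <- list.files(case_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0)
    stop(sprintf("no NIfTI files in %s", case_dir), call. = FALSE)
  vols <- lapply(files, read_volume)
  mods <- vapply(vols, `[[`, character(1), "modality")
  seg <- vols[[match("seg", mods)]]
  img_idx <- match(spec$modality, mods)
  if (is.na(img_idx)) img_idx <- match("synthetic", mods)
  if (is.na(img_idx) || is.na(match("seg", mods)))
    stop(sprintf("case %s lacks a %s or seg volume", case_dir, spec$modality),
         call. = FALSE)
  img_vol <- vols[[img_idx]]
  img_slices <- slice_volume(img_vol)
  lab_slices <- slice_volume(seg)
  out <- vector("list", length(img_slices))
  for (i in seq_along(img_slices)) {
    m <- extract_target_mask(lab_slices[[i]], spec)
    out[[i]] <- slice_sample(normalize_slice(img_slices[[i]]), m,
                             case_id = img_vol$case_id, slice_index = i - 1L,
                             modality = img_vol$modality, target = spec$target)
  }
  if (drop_empty)
    out <- Filter(function(s) sum(s$mask) > 0, out)
  out
}
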