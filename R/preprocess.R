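#' Tumor-masked 4-channel axial slices of one patient
#'
#' For every axial index, each modality slice is multiplied by the binary
#' whole-tumor slice; slices with no tumor pixels are omitted.
#'
#' @param volume a [multimodal_volume()].
#' @param mask the matching [segmentation_mask()].
#' @param grade optional grade label attached to each slice.
#' @return list of `slice_sample` objects: `image` (H x W x 4, channel
#'   order T1, T2, T1-Gd, FLAIR; non-tumor pixels exactly zero),
#'   `patient_id`, `grade`, `axial_index`, `tumor_pixels`.
#' @export
masked_axial_slices <- function(volume, mask, grade = NA_character_) {
  stopifnot(inherits(volume, "multimodal_volume"),
            inherits(mask, "segmentation_mask"))
  if (!identical(dim(volume$t1), dim(mask$labels)))
    stop2("volume and mask grids differ", class = "grid_consistency_error")
  tumor <- mask$labels %in% c(1L, 2L, 4L)
  dim(tumor) <- dim(mask$labels)
  nz <- dim(tumor)[3]
  out <- list()
  for (k in seq_len(nz)) {
    tk <- tumor[, , k]
    npix <- sum(tk)
    if (npix == 0) next
    img <- array(0, c(dim(tk), 4L))
    for (ci in seq_along(nifti_modalities))
      img[, , ci] <- volume[[nifti_modalities[ci]]][, , k] * tk
    out[[length(out) + 1L]] <- structure(list(
      image = img, patient_id = volume$patient_id, grade = grade,
      axial_index = k, tumor_pixels = npix
    ), class = "slice_sample")
  }
  if (!length(out)) warning("empty tumor: no axial slices extracted")
  out
}

#' Drop slices whose tumor area is below a pixel threshold
#'
#' @param slices list of `slice_sample`s.
#' @param min_tumor_pixels minimum tumor pixel count to keep a slice.
#' @return filtered list (possibly empty, with a warning).
#' @export
drop_small_tumor_slices <- function(slices, min_tumor_pixels = 100L) {
  if (min_tumor_pixels < 0)
    stop2("min_tumor_pixels must be >= 0", class = "validation_error")
  keep <- vapply(slices, function(s) s$tumor_pixels >= min_tumor_pixels, TRUE)
  out <- slices[keep]
  if (!length(out)) warning("all slices dropped by the tumor-size filter")
  out
}

#' Patient-level stratified train/validation split
#'
#' Per grade, `floor(ratio * n)` patients go to training and the
#' remainder to validation; deterministic given the seed.
#'
#' @param manifest cohort manifest data.frame with patient_id and grade.
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @return list of class `cohort_split` with `train_ids`, `val_ids`,
#'   `ratio`, `seed`.
#' @export
split_by_patient <- function(manifest, ratio = 0.7, seed = 1L) {
  if (ratio <= 0 || ratio >= 1)
    stop2("ratio must lie strictly inside (0,1)", class = "validation_error")
  counts <- table(manifest$grade)
  if (length(counts) < 2 || any(counts < 2))
    stop2("each grade needs at least 2 patients to split",
          class = "validation_error")
  train_ids <- character(0)
  with_seed(seed, {
    for (g in sort(names(counts))) {
      ids <- manifest$patient_id[manifest$grade == g]
      n_train <- floor(ratio * length(ids))
      train_ids <- c(train_ids, sample(ids, n_train))
    }
  })
  structure(list(train_ids = sort(train_ids),
                 val_ids = sort(setdiff(manifest$patient_id, train_ids)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "cohort_split")
}

#' Balance slice counts by duplicating minority-class samples
#'
#' Minority-class slices are duplicated round-robin until the two class
#' slice counts agree within one. Duplicates carry `duplicate = TRUE` so
#' the training loop can re-randomize their augmentation independently;
#' majority-class samples are returned untouched.
#'
#' @param samples list of `slice_sample`s with a `grade` field.
#' @return list of `slice_sample`s.
#' @export
upsample_minority <- function(samples) {
  grades <- vapply(samples, `[[`, character(1), "grade")
  counts <- table(grades)
  if (length(counts) < 2)
    stop2("both classes must be present for upsampling",
          class = "validation_error")
  minority <- names(counts)[which.min(counts)]
  deficit <- max(counts) - min(counts)
  if (deficit == 0) return(samples)
  pool <- samples[grades == minority]
  extra <- lapply(seq_len(deficit), function(i) {
    s <- pool[[((i - 1) %% length(pool)) + 1]]
    s$duplicate <- TRUE
    s
  })
  c(samples, extra)
}
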