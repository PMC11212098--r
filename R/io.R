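#' Four co-registered modality grids
#'
#' @param t1,t2,t1gd,flair 3D numeric arrays sharing one shape.
#' @param spacing_mm three positive voxel spacings (mm).
#' @param patient_id string.
#' @return object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(t1, t2, t1gd, flair, spacing_mm, patient_id = "") {
  grids <- list(t1 = t1, t2 = t2, t1gd = t1gd, flair = flair)
  dims <- lapply(grids, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stop2("modality grids must be 3D arrays", class = "validation_error")
  for (m in names(grids))
    if (!identical(dims[[m]], dims$t1))
      stop2("grid shape of '%s' differs from t1", m, class = "grid_consistency_error")
  check_positive(spacing_mm, "spacing_mm")
  structure(c(grids, list(spacing_mm = as.numeric(spacing_mm),
                          patient_id = patient_id)),
            class = "multimodal_volume")
}

#' Integer-labelled tumor segmentation (BraTS convention)
#'
#' Labels: 0 background, 1 necrotic core, 2 edema, 4 enhancing tumor.
#'
#' @param labels 3D integer array.
#' @param spacing_mm three positive voxel spacings (mm).
#' @return object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels, spacing_mm) {
  if (length(dim(labels)) != 3)
    stop2("labels must be a 3D array", class = "validation_error")
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L, 4L))
  if (length(bad))
    stop2("mask contains labels outside {0,1,2,4}: %s",
          paste(bad, collapse = ", "), class = "label_error")
  check_positive(spacing_mm, "spacing_mm")
  structure(list(labels = labels, spacing_mm = as.numeric(spacing_mm)),
            class = "segmentation_mask")
}

nifti_modalities <- c("t1", "t2", "t1gd", "flair")

#' Write a synthetic patient's volumes and mask as NIfTI
#'
#' @param patient a `synthetic_patient`.
#' @param out_dir output directory.
#' @return named character vector of written file paths (t1, t2, t1gd,
#'   flair, mask).
#' @export
write_patient <- function(patient, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- patient$volumes$spacing_mm
  paths <- c()
  for (m in nifti_modalities) {
    p <- file.path(out_dir, sprintf("%s_%s.nii.gz", patient$patient_id, m))
    RNifti::writeNifti(RNifti::asNifti(patient$volumes[[m]], pixdim = sp), p)
    paths[m] <- p
  }
  p <- file.path(out_dir, sprintf("%s_seg.nii.gz", patient$patient_id))
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(patient$mask$labels), dim(patient$mask$labels)),
                    pixdim = sp, datatype = "int16"), p)
  paths["mask"] <- p
  paths
}

#' Read a patient from one manifest row
#'
#' Loads the four modality NIfTIs and the segmentation, enforcing mutual
#' grid consistency and the BraTS label set.
#'
#' @param row one-row data.frame with columns t1_path, t2_path, t1gd_path,
#'   flair_path, mask_path, patient_id, grade, os_months, event.
#' @return list with `volume` ([multimodal_volume()]), `mask`
#'   ([segmentation_mask()]) and `meta` (patient_id, grade, os_months,
#'   event).
#' @export
read_patient <- function(row) {
  row <- as.list(row)
  path_cols <- c(t1 = "t1_path", t2 = "t2_path", t1gd = "t1gd_path",
                 flair = "flair_path", mask = "mask_path")
  imgs <- list()
  for (m in names(path_cols)) {
    p <- row[[path_cols[[m]]]]
    if (is.null(p) || is.na(p) || !file.exists(p))
      stop2("file for '%s' not found: %s", m, p %||% "<missing>",
            class = "data_error")
    imgs[[m]] <- RNifti::readNifti(p)
  }
  ref_dim <- dim(imgs$t1)
  for (m in names(imgs))
    if (!identical(dim(imgs[[m]]), ref_dim))
      stop2("grid shape of '%s' (%s) does not match t1 (%s)",
            basename(row[[path_cols[[m]]]]),
            paste(dim(imgs[[m]]), collapse = "x"),
            paste(ref_dim, collapse = "x"),
            class = "grid_consistency_error")
  sp <- RNifti::pixdim(imgs$t1)[1:3]
  vol <- multimodal_volume(array(as.numeric(imgs$t1), ref_dim),
                           array(as.numeric(imgs$t2), ref_dim),
                           array(as.numeric(imgs$t1gd), ref_dim),
                           array(as.numeric(imgs$flair), ref_dim),
                           spacing_mm = sp,
                           patient_id = row$patient_id %||% "")
  mask <- segmentation_mask(array(as.integer(round(as.numeric(imgs$mask))), ref_dim),
                            spacing_mm = sp)
  list(volume = vol, mask = mask,
       meta = list(patient_id = row$patient_id, grade = row$grade,
                   os_months = row$os_months, event = row$event))
}

#' Read a cohort manifest CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Export axial slices of every modality as 8-bit grayscale PNGs
#'
#' One PNG per axial index per modality; intensities are windowed to
#' `[0, 255]` by the per-volume min-max. A constant volume yields
#' all-black images (a message is emitted).
#'
#' @param volume a [multimodal_volume()].
#' @param out_dir output directory.
#' @return character vector of written file paths (one per modality per
#'   axial slice).
#' @export
export_slices_png <- function(volume, out_dir) {
  stopifnot(inherits(volume, "multimodal_volume"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  nz <- dim(volume$t1)[3]
  for (m in nifti_modalities) {
    g <- volume[[m]]
    rng <- range(g)
    if (rng[1] == rng[2]) {
      message("constant '", m, "' volume: exporting all-black PNGs")
      g01 <- array(0, dim(g))
    } else {
      g01 <- (g - rng[1]) / (rng[2] - rng[1])
    }
    for (k in seq_len(nz)) {
      p <- file.path(out_dir, sprintf("%s_%s_%03d.png",
                                      volume$patient_id, m, k))
      png::writePNG(g01[, , k], p)
      files <- c(files, p)
    }
  }
  files
}
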