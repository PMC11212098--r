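#' Default per-modality, per-tissue contrast means
#'
#' Rows are the four modalities, columns the four tissue classes. Values
#' are arbitrary-unit intensities chosen to mimic the qualitative contrast
#' behaviour of each sequence: necrosis dark on T1 and T1-Gd, edema and
#' necrosis bright on T2, the enhancing rim bright on gadolinium T1,
#' edema bright on FLAIR.
#'
#' @return 4x4 numeric matrix with dimnames.
#' @export
default_modality_contrast <- function() {
  m <- rbind(
    t1    = c(background = 100, necrosis =  60, edema =  80, enhancing = 110),
    t2    = c(background = 100, necrosis = 160, edema = 180, enhancing = 140),
    t1gd  = c(background = 100, necrosis =  50, edema =  85, enhancing = 200),
    flair = c(background = 100, necrosis =  90, edema = 190, enhancing = 150)
  )
  m
}

#' Specification of a synthetic phantom cohort
#'
#' Describes the study conditions for the phantom generator: grid geometry,
#' per-grade tumor size and lobularity, modality contrast, image noise,
#' per-grade overall-survival scales and the censoring rate. Defaults give
#' a desk-scale 64x64x48 grid; pass `grid_shape = c(240, 240, 155)` for
#' full-scale volumes.
#'
#' Low-grade phantoms are single ellipsoids with radii drawn from
#' `lgg_radius_mm`; high-grade phantoms are unions of `lobe_count_hgg`
#' overlapping ellipsoids with radii from the strictly larger
#' `hgg_radius_mm`, which makes them both larger and more irregular.
#' Survival is exponential with grade-dependent scale (months), LGG scale
#' larger than HGG.
#'
#' @param grid_shape three positive integers (voxels).
#' @param spacing_mm three positive voxel spacings in mm.
#' @param n_lgg,n_hgg non-negative patient counts per grade.
#' @param lgg_radius_mm,hgg_radius_mm radius ranges (mm); the HGG range
#'   must sit strictly above the LGG range.
#' @param lobe_count_hgg integer range (>= 1) of ellipsoid lobes per HGG
#'   tumor.
#' @param modality_contrast 4x4 matrix as [default_modality_contrast()].
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param os_scale_months named c(LGG=, HGG=) exponential scales, LGG > HGG.
#' @param censor_prob probability a survival time is censored, in [0,1].
#' @param seed integer cohort seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing_mm = c(1, 1, 1),
                         n_lgg = 5, n_hgg = 5,
                         lgg_radius_mm = c(5, 10),
                         hgg_radius_mm = c(12, 20),
                         lobe_count_hgg = c(2, 4),
                         modality_contrast = default_modality_contrast(),
                         noise_sd = 5,
                         os_scale_months = c(LGG = 60, HGG = 19),
                         censor_prob = 0.2,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3) stop2("grid_shape must have length 3", class = "validation_error")
  check_positive(grid_shape, "grid_shape")
  check_positive(spacing_mm, "spacing_mm")
  if (n_lgg < 0 || n_hgg < 0)
    stop2("patient counts must be non-negative", class = "validation_error")
  lgg_radius_mm <- check_range(lgg_radius_mm, "lgg_radius_mm")
  hgg_radius_mm <- check_range(hgg_radius_mm, "hgg_radius_mm")
  check_positive(c(lgg_radius_mm[1], hgg_radius_mm[1]), "radius ranges")
  if (hgg_radius_mm[1] <= lgg_radius_mm[1] || hgg_radius_mm[2] <= lgg_radius_mm[2])
    stop2("hgg_radius_mm must be strictly larger than lgg_radius_mm",
          class = "validation_error")
  lobe_count_hgg <- check_range(lobe_count_hgg, "lobe_count_hgg")
  if (lobe_count_hgg[1] < 1)
    stop2("lobe_count_hgg must be >= 1", class = "validation_error")
  if (!is.matrix(modality_contrast) || !all(dim(modality_contrast) == c(4, 4)))
    stop2("modality_contrast must be a 4x4 matrix", class = "validation_error")
  if (noise_sd < 0) stop2("noise_sd must be >= 0", class = "validation_error")
  check_positive(os_scale_months, "os_scale_months")
  if (os_scale_months[["LGG"]] <= os_scale_months[["HGG"]])
    stop2("os_scale_months must have LGG > HGG", class = "validation_error")
  if (censor_prob < 0 || censor_prob > 1)
    stop2("censor_prob must lie in [0,1]", class = "validation_error")
  structure(list(
    grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
    n_lgg = as.integer(n_lgg), n_hgg = as.integer(n_hgg),
    lgg_radius_mm = lgg_radius_mm, hgg_radius_mm = hgg_radius_mm,
    lobe_count_hgg = lobe_count_hgg,
    modality_contrast = modality_contrast,
    noise_sd = noise_sd, os_scale_months = os_scale_months,
    censor_prob = censor_prob, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Distance field: for each voxel center the minimum over lobes of the
# normalised ellipsoid radial coordinate rho (<= 1 inside the lobe).
lobe_rho <- function(spec, lobes) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  cx <- (seq_len(d[1]) - 1) * sp[1]
  cy <- (seq_len(d[2]) - 1) * sp[2]
  cz <- (seq_len(d[3]) - 1) * sp[3]
  rho <- array(Inf, d)
  for (lb in lobes) {
    dx2 <- ((cx - lb$center_mm[1]) / lb$radii_mm[1])^2
    dy2 <- ((cy - lb$center_mm[2]) / lb$radii_mm[2])^2
    dz2 <- ((cz - lb$center_mm[3]) / lb$radii_mm[3])^2
    r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
    rho <- pmin(rho, r)
  }
  rho
}

# rho thresholds partitioning the tumor into necrosis core (label 1),
# enhancing rim (label 4) and an edema collar (label 2)
.rho_necrosis <- 0.55
.rho_edema <- 1.35

#' Generate one synthetic patient
#'
#' Builds the tumor as a union of one (LGG) or several (HGG) overlapping
#' ellipsoids, partitions its interior into necrosis core / enhancing rim
#' / edema collar with BraTS labels 1/4/2, renders the four modality
#' volumes as per-tissue contrast means plus Gaussian noise, and draws an
#' exponential survival time with the grade's scale.
#'
#' @param spec a [phantom_spec()].
#' @param grade `"LGG"` or `"HGG"`.
#' @param patient_id string; also keys the patient's private RNG stream.
#' @return list of class `synthetic_patient` with fields `patient_id`,
#'   `volumes` ([multimodal_volume()]), `mask` ([segmentation_mask()]),
#'   `grade`, `os_months`, `event`, and `geometry` (the sampled lobes).
#' @export
generate_patient <- function(spec, grade, patient_id = paste0(grade, "-001")) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!grade %in% c("LGG", "HGG"))
    stop2("grade must be LGG or HGG", class = "validation_error")
  with_seed(patient_seed(spec$seed, patient_id), {
    d <- spec$grid_shape; sp <- spec$spacing_mm
    extent_mm <- (d - 1) * sp
    rng_r <- if (grade == "LGG") spec$lgg_radius_mm else spec$hgg_radius_mm
    n_lobes <- if (grade == "LGG") 1L else
      as.integer(round(draw_range(spec$lobe_count_hgg)))
    # primary lobe near the grid center, satellites offset from it;
    # radii clipped so the edema collar stays inside the grid
    max_r <- pmax(1e-6, extent_mm / 2 / .rho_edema - 1)
    ctr0 <- extent_mm / 2 + runif(3, -0.05, 0.05) * extent_mm
    lobes <- vector("list", n_lobes)
    for (i in seq_len(n_lobes)) {
      radii <- pmin(draw_range(rng_r, 3), max_r)
      ctr <- if (i == 1) ctr0 else
        ctr0 + runif(3, -0.5, 0.5) * lobes[[1]]$radii_mm
      lo <- ctr - radii * .rho_edema; hi <- ctr + radii * .rho_edema
      shift <- pmax(0, -lo) - pmax(0, hi - extent_mm)
      lobes[[i]] <- list(center_mm = ctr + shift, radii_mm = radii)
    }
    rho <- lobe_rho(spec, lobes)
    labels <- array(0L, d)
    labels[rho <= .rho_edema] <- 2L
    labels[rho <= 1] <- 4L
    labels[rho <= .rho_necrosis] <- 1L
    if (!any(labels > 0L))
      stop2("degenerate phantom: empty tumor", class = "validation_error")
    tissue_col <- c("background", "necrosis", "edema", "background", "enhancing")
    tidx <- tissue_col[labels + 1L]
    mods <- rownames(spec$modality_contrast)
    grids <- lapply(mods, function(m) {
      g <- array(spec$modality_contrast[m, tidx], d)
      if (spec$noise_sd > 0) g <- g + array(rnorm(prod(d), 0, spec$noise_sd), d)
      g
    })
    names(grids) <- mods
    os <- rexp(1, rate = 1 / spec$os_scale_months[[grade]])
    ev <- rbinom(1, 1, 1 - spec$censor_prob)
    structure(list(
      patient_id = patient_id,
      volumes = multimodal_volume(grids$t1, grids$t2, grids$t1gd, grids$flair,
                                  spacing_mm = sp, patient_id = patient_id),
      mask = segmentation_mask(labels, spacing_mm = sp),
      grade = grade, os_months = os, event = ev,
      geometry = lobes
    ), class = "synthetic_patient")
  })
}

#' Generate a phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @param out_dir optional directory; when given, NIfTI volumes and a CSV
#'   manifest (`manifest.csv`) are written there.
#' @return list with `patients` (list of [generate_patient()] results) and
#'   `manifest` (data.frame with columns patient_id, t1_path, t2_path,
#'   t1gd_path, flair_path, mask_path, grade, os_months, event).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_lgg + spec$n_hgg
  if (n < 1) stop2("cohort must contain at least one patient", class = "validation_error")
  ids <- c(sprintf("LGG-%03d", seq_len(spec$n_lgg)),
           sprintf("HGG-%03d", seq_len(spec$n_hgg)))
  grades <- c(rep("LGG", spec$n_lgg), rep("HGG", spec$n_hgg))
  patients <- Map(function(id, g) generate_patient(spec, g, id), ids, grades)
  manifest <- data.frame(
    patient_id = ids,
    t1_path = NA_character_, t2_path = NA_character_,
    t1gd_path = NA_character_, flair_path = NA_character_,
    mask_path = NA_character_,
    grade = grades,
    os_months = vapply(patients, `[[`, numeric(1), "os_months"),
    event = vapply(patients, `[[`, numeric(1), "event"),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(patients)) {
      paths <- write_patient(patients[[i]], out_dir)
      manifest$t1_path[i] <- paths[["t1"]]
      manifest$t2_path[i] <- paths[["t2"]]
      manifest$t1gd_path[i] <- paths[["t1gd"]]
      manifest$flair_path[i] <- paths[["flair"]]
      manifest$mask_path[i] <- paths[["mask"]]
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(patients = patients, manifest = manifest)
}
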