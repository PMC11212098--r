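#' Configuration for an end-to-end run
#'
#' @param spec a [phantom_spec()] describing the synthetic cohort, or
#'   `NULL` when `manifest_path` points at an existing cohort.
#' @param manifest_path optional path to a cohort manifest CSV with
#'   resolvable NIfTI paths.
#' @param out_dir run directory (created).
#' @param split_ratio training fraction (default 0.7).
#' @param split_seed patient-split seed.
#' @param min_tumor_pixels slice-level tumor-size filter (default 100).
#' @param min_slices case-level minimum surviving slice count (default 1).
#' @param augment an [augment_config()] or `NULL` to disable
#'   augmentation.
#' @param train a [train_config()].
#' @param backbone a [tiny_backbone()].
#' @param write_nifti if `TRUE`, a simulated cohort is also materialized
#'   as NIfTI files under `out_dir/data`; by default the volumes stay in
#'   memory and only the manifest and derived outputs are written.
#' @return object of class `run_config`.
#' @export
run_config <- function(spec = phantom_spec(n_lgg = 6, n_hgg = 6),
                       manifest_path = NULL,
                       out_dir = tempfile("gliomafuse_run_"),
                       split_ratio = 0.7, split_seed = 1L,
                       min_tumor_pixels = 100L, min_slices = 1L,
                       augment = augment_config(),
                       train = train_config(),
                       backbone = tiny_backbone(),
                       write_nifti = FALSE) {
  if (is.null(spec) && is.null(manifest_path))
    stop2("either a phantom spec or a manifest path is required",
          class = "validation_error")
  if (!is.null(manifest_path) && !file.exists(manifest_path))
    stop2("manifest not found: %s", manifest_path, class = "validation_error")
  structure(list(spec = spec, manifest_path = manifest_path,
                 out_dir = out_dir, split_ratio = split_ratio,
                 split_seed = as.integer(split_seed),
                 min_tumor_pixels = as.integer(min_tumor_pixels),
                 min_slices = as.integer(min_slices),
                 augment = augment, train = train, backbone = backbone,
                 write_nifti = isTRUE(write_nifti)),
            class = "run_config")
}

# load slices + attach patient-level shape features
build_samples <- function(patients, manifest, features, min_tumor_pixels,
                          min_slices) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    if (!is.null(patients)) {
      vol <- patients[[i]]$volumes; mask <- patients[[i]]$mask
    } else {
      pr <- read_patient(manifest[i, ])
      vol <- pr$volume; mask <- pr$mask
    }
    sl <- masked_axial_slices(vol, mask, grade = manifest$grade[i])
    sl <- drop_small_tumor_slices(sl, min_tumor_pixels)
    if (length(sl) < min_slices) {
      warning(sprintf("patient %s excluded: %d slices after filtering",
                      pid, length(sl)))
      next
    }
    fv <- as.numeric(features[features$patient_id == pid,
                              shape_feature_names()])
    sl <- lapply(sl, function(s) { s$shape_features <- fv; s })
    out <- c(out, sl)
  }
  out
}

#' Run the whole pipeline: simulate/load, features, split, train,
#' evaluate, survival, explain
#'
#' Stages write their outputs (manifest.csv, features.csv, split.json,
#' model.rds, report.json, survival.json, heatmap PNGs, run.log) into the
#' run directory; a stage failure aborts with the failing stage named,
#' retaining partial outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the run directory, the fitted model,
#'   the patient predictions, the `metrics_report` and the survival
#'   results.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                file = logf, append = TRUE)
  stage <- function(name, expr) {
    say("[%s] start", name)
    tryCatch(expr, error = function(e) {
      say("[%s] FAILED: %s", name, conditionMessage(e))
      stop2("stage '%s' failed: %s", name, conditionMessage(e),
            class = "stage_error")
    })
  }

  patients <- NULL
  manifest <- stage("simulate", {
    if (!is.null(config$spec)) {
      cohort <- generate_cohort(
        config$spec,
        out_dir = if (config$write_nifti) file.path(config$out_dir, "data"))
      patients <- cohort$patients
      write.csv(cohort$manifest, file.path(config$out_dir, "manifest.csv"),
                row.names = FALSE)
      cohort$manifest
    } else {
      m <- read_manifest(config$manifest_path)
      write.csv(m, file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
      m
    }
  })

  features <- stage("features", {
    ft <- shape_feature_table(manifest, patients)
    write.csv(ft, file.path(config$out_dir, "features.csv"), row.names = FALSE)
    ft
  })

  split <- stage("split", {
    sp <- split_by_patient(manifest, config$split_ratio, config$split_seed)
    jsonlite::write_json(sp[c("train_ids", "val_ids", "ratio", "seed")],
                         file.path(config$out_dir, "split.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    sp
  })

  samples <- stage("preprocess", {
    build_samples(patients, manifest, features,
                  config$min_tumor_pixels, config$min_slices)
  })
  pid_of <- vapply(samples, `[[`, character(1), "patient_id")
  train_samples <- samples[pid_of %in% split$train_ids]
  val_samples <- samples[pid_of %in% split$val_ids]

  model <- stage("train", {
    ts <- train_samples
    if (!is.null(config$augment) && config$augment$enable_duplication)
      ts <- upsample_minority(ts)
    m <- fusion_fit(ts, config$train, config$backbone, config$augment)
    saveRDS(m, file.path(config$out_dir, "model.rds"))
    write.csv(m$training_log, file.path(config$out_dir, "training_log.csv"),
              row.names = FALSE)
    m
  })

  report <- stage("evaluate", {
    sp <- predict_slices(model, val_samples)
    pp <- aggregate_by_patient(sp)
    rep <- metrics_report(pp)
    jsonlite::write_json(
      list(metrics = list(auc = rep$auc, acc = rep$acc, apca = rep$apca,
                          sen = rep$sen, spe = rep$spe),
           confusion = as.list(rep$confusion),
           roc_points = rep$roc_points,
           channels = model$channels,
           seed = config$train$seed),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(patient_predictions = pp, report = rep)
  })

  surv <- stage("survival", {
    sv <- survival_analysis(manifest)
    jsonlite::write_json(
      list(logrank = list(chi_square = sv$logrank$chi_square,
                          p_value = sv$logrank$p_value),
           km = lapply(sv$km, function(k)
             list(time = k$time, surv = k$surv))),
      file.path(config$out_dir, "survival.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    sv
  })

  stage("explain", {
    vp <- val_samples[vapply(val_samples, `[[`, character(1), "grade") == "HGG"]
    if (length(vp)) {
      hm <- activation_heatmap(model, vp[[1]], "HGG")
      write_heatmap_png(hm, vp[[1]]$image,
                        file.path(config$out_dir,
                                  paste0("heatmap_", vp[[1]]$patient_id)))
    }
  })

  say("run complete")
  invisible(list(out_dir = config$out_dir, model = model,
                 patient_predictions = report$patient_predictions,
                 report = report$report, survival = surv,
                 split = split))
}

#' Augmentation ablation matrix
#'
#' Re-runs the pipeline once per ablation row with a shared split and
#' seed: no augmentation at all, each augmentation component disabled in
#' turn, and the full configuration.
#'
#' @param config a [run_config()]; each row writes into a subdirectory
#'   of `config$out_dir`.
#' @return data.frame with columns row and auc (patient-level).
#' @export
ablation_matrix <- function(config) {
  stopifnot(inherits(config, "run_config"))
  base_aug <- config$augment %||% augment_config()
  rows <- list(
    "w/o Augment" = NULL,
    "w/o CyclicShift" = { a <- base_aug; a$enable_cyclic_shift <- FALSE; a },
    "w/o Rotation" = { a <- base_aug; a$enable_rotation <- FALSE; a },
    "w/o Flip" = { a <- base_aug; a$enable_flip <- FALSE; a },
    "w/o Duplication" = { a <- base_aug; a$enable_duplication <- FALSE; a },
    "Our work" = base_aug
  )
  out <- data.frame(row = names(rows), auc = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rows)) {
    cfg <- config
    cfg$augment <- rows[[i]]
    cfg$out_dir <- file.path(config$out_dir,
                             gsub("[^A-Za-z]+", "_", names(rows)[i]))
    res <- run_end_to_end(cfg)
    out$auc[i] <- res$report$auc
  }
  out
}
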