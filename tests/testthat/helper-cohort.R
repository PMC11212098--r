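# Shared fixtures built in code. The slice-sample builder mirrors the
# pipeline's preprocess stage; the small trained model is memoized so
# several test files can reuse it without retraining.

.fixture_env <- new.env(parent = emptyenv())

make_cohort_samples <- function(spec, min_tumor_pixels = 100L) {
  co <- generate_cohort(spec)
  ft <- shape_feature_table(co$manifest, co$patients)
  samples <- list()
  for (i in seq_len(nrow(co$manifest))) {
    sl <- masked_axial_slices(co$patients[[i]]$volumes, co$patients[[i]]$mask,
                              co$manifest$grade[i])
    sl <- drop_small_tumor_slices(sl, min_tumor_pixels)
    fv <- as.numeric(ft[i, shape_feature_names()])
    samples <- c(samples, lapply(sl, function(s) {
      s$shape_features <- fv
      s
    }))
  }
  list(samples = samples, manifest = co$manifest, features = ft,
       patients = co$patients)
}

# 40-patient volume-separable cohort shared by the recovery checks
volume_cohort_fixture <- function() {
  fx <- .fixture_env$volume_cohort
  if (!is.null(fx)) return(fx)
  spec <- phantom_spec(n_lgg = 20, n_hgg = 20, seed = 2024)
  ch <- make_cohort_samples(spec)
  split <- split_by_patient(ch$manifest, 0.7, seed = 2024)
  pid <- vapply(ch$samples, `[[`, character(1), "patient_id")
  fx <- list(cohort = ch, split = split,
             train = ch$samples[pid %in% split$train_ids],
             val = ch$samples[pid %in% split$val_ids])
  .fixture_env$volume_cohort <- fx
  fx
}

patient_auc <- function(model, val_samples) {
  pp <- aggregate_by_patient(predict_slices(model, val_samples))
  names(pp)[names(pp) == "true_grade"] <- "true_grade"
  roc_auc(pp)$auc
}

small_trained_fixture <- function() {
  fx <- .fixture_env$small_model
  if (!is.null(fx)) return(fx)
  spec <- phantom_spec(n_lgg = 4, n_hgg = 4, seed = 11)
  ch <- make_cohort_samples(spec)
  model <- fusion_fit(upsample_minority(ch$samples),
                      train_config(epochs = 2, seed = 5),
                      tiny_backbone(), augment_config())
  fx <- list(cohort = ch, model = model)
  .fixture_env$small_model <- fx
  fx
}
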