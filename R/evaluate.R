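#' Aggregate slice probabilities into patient predictions
#'
#' Arithmetic mean of the slice probability pairs per patient; predicted
#' grade is the argmax with ties resolved toward HGG.
#'
#' @param slice_preds data.frame with patient_id, grade, p_lgg, p_hgg
#'   (as returned by [predict_slices()]).
#' @return data.frame with one row per patient: patient_id, true_grade,
#'   p_lgg, p_hgg, predicted_grade.
#' @export
aggregate_by_patient <- function(slice_preds) {
  keep <- !is.na(slice_preds$p_hgg)
  if (!all(keep)) {
    warning("excluding slices with missing probabilities")
    slice_preds <- slice_preds[keep, ]
  }
  ids <- unique(slice_preds$patient_id)
  rows <- lapply(ids, function(id) {
    s <- slice_preds[slice_preds$patient_id == id, ]
    p <- c(mean(s$p_lgg), mean(s$p_hgg))
    p <- p / sum(p)
    data.frame(patient_id = id, true_grade = s$grade[1],
               p_lgg = p[1], p_hgg = p[2],
               predicted_grade = if (p[2] >= p[1]) "HGG" else "LGG",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Confusion matrix and threshold metrics (positive class HGG)
#'
#' Accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and average per-class accuracy `(sen+spe)/2`. A metric
#' whose defining class is absent is reported as `NA`, never 0.
#'
#' @param patient_preds data.frame from [aggregate_by_patient()] (needs
#'   true_grade and predicted_grade).
#' @return list with `confusion` (named tp/fn/fp/tn) and `metrics`
#'   (named acc/apca/sen/spe).
#' @export
confusion_and_metrics <- function(patient_preds) {
  truth <- patient_preds$true_grade
  pred <- patient_preds$predicted_grade
  tp <- sum(truth == "HGG" & pred == "HGG")
  fn <- sum(truth == "HGG" & pred == "LGG")
  fp <- sum(truth == "LGG" & pred == "HGG")
  tn <- sum(truth == "LGG" & pred == "LGG")
  n <- tp + fn + fp + tn
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  apca <- if (!is.na(sen) && !is.na(spe)) (sen + spe) / 2 else NA_real_
  list(confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
       metrics = c(acc = (tp + tn) / n, apca = apca, sen = sen, spe = spe))
}

#' ROC curve and AUC (rank formulation, HGG score)
#'
#' AUC by the Mann-Whitney rank statistic with half credit for ties;
#' the ROC polyline comes from a threshold sweep over the unique scores.
#'
#' @param patient_preds data.frame with true_grade and p_hgg.
#' @return list with `auc` and `roc_points` (data.frame fpr, tpr,
#'   monotone nondecreasing in both coordinates).
#' @export
roc_auc <- function(patient_preds) {
  score <- patient_preds$p_hgg
  pos <- patient_preds$true_grade == "HGG"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop2("AUC undefined: both classes must be present",
          class = "undefined_auc_error")
  r <- rank(score)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    c(fpr = sum(!pos & score >= t) / nn, tpr = sum(pos & score >= t) / np)
  }, c(fpr = 0, tpr = 0)))
  pts <- rbind(c(0, 0), pts, c(1, 1))
  list(auc = auc,
       roc_points = data.frame(fpr = pts[, 1], tpr = pts[, 2]))
}

#' Full patient-level metrics report
#'
#' @param patient_preds data.frame from [aggregate_by_patient()].
#' @return list of class `metrics_report`: auc, acc, apca, sen, spe,
#'   confusion, roc_points.
#' @export
metrics_report <- function(patient_preds) {
  cm <- confusion_and_metrics(patient_preds)
  ra <- roc_auc(patient_preds)
  structure(c(list(auc = ra$auc), as.list(cm$metrics),
              list(confusion = cm$confusion, roc_points = ra$roc_points)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.4f  Acc %.4f  APCA %.4f  SEN %.4f  SPE %.4f\n",
              x$auc, x$acc, x$apca, x$sen, x$spe))
  cm <- x$confusion
  cat(sprintf("confusion (positive = HGG): tp=%d fn=%d fp=%d tn=%d\n",
              cm["tp"], cm["fn"], cm["fp"], cm["tn"]))
  invisible(x)
}
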