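slice_df <- function(pid, grade, plgg) {
  data.frame(patient_id = pid, grade = grade,
             p_lgg = plgg, p_hgg = 1 - plgg, stringsAsFactors = FALSE)
}

test_that("patient aggregation averages slice probabilities; ties go to HGG", {
  sp <- slice_df(c("a", "a"), "HGG", c(0.2, 0.4))
  pp <- aggregate_by_patient(sp)
  expect_equal(pp$p_lgg, 0.3)
  expect_equal(pp$p_hgg, 0.7)
  expect_equal(pp$predicted_grade, "HGG")
  one <- aggregate_by_patient(slice_df("b", "LGG", 0.9))
  expect_equal(one$p_lgg, 0.9)
  expect_equal(one$predicted_grade, "LGG")
  tie <- aggregate_by_patient(slice_df("c", "LGG", 0.5))
  expect_equal(tie$predicted_grade, "HGG")
})

make_patient_preds <- function(n_hgg_correct, n_hgg_wrong,
                               n_lgg_correct, n_lgg_wrong) {
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n_hgg_correct + n_hgg_wrong +
                                            n_lgg_correct + n_lgg_wrong)),
    true_grade = c(rep("HGG", n_hgg_correct + n_hgg_wrong),
                   rep("LGG", n_lgg_correct + n_lgg_wrong)),
    predicted_grade = c(rep("HGG", n_hgg_correct), rep("LGG", n_hgg_wrong),
                        rep("LGG", n_lgg_correct), rep("HGG", n_lgg_wrong)),
    stringsAsFactors = FALSE)
}

test_that("the 121/34 validation worked example reproduces the published metrics", {
  pp <- make_patient_preds(121, 0, 33, 1)
  cm <- confusion_and_metrics(pp)
  expect_identical(unname(cm$confusion), c(121L, 0L, 1L, 33L))
  expect_equal(cm$metrics[["acc"]], 0.9936, tolerance = 1e-4)
  expect_equal(round(cm$metrics[["apca"]], 4), 0.9853)
  expect_equal(round(cm$metrics[["sen"]], 4), 1.0000)
  expect_equal(round(cm$metrics[["spe"]], 4), 0.9706)
})

test_that("the all-HGG baseline reaches about 78% accuracy on the imbalanced cohort", {
  pp <- make_patient_preds(121, 0, 0, 34)
  cm <- confusion_and_metrics(pp)
  expect_equal(cm$metrics[["acc"]], 121 / 155)
  expect_equal(round(cm$metrics[["acc"]], 2), 0.78)
  expect_equal(cm$metrics[["spe"]], 0)
  expect_equal(cm$metrics[["apca"]], 0.5)
})

test_that("perfect predictions score 1 everywhere; absent classes give NA", {
  pp <- make_patient_preds(10, 0, 5, 0)
  cm <- confusion_and_metrics(pp)
  expect_equal(unname(cm$metrics), c(1, 1, 1, 1))
  only_hgg <- make_patient_preds(5, 1, 0, 0)
  cm2 <- confusion_and_metrics(only_hgg)
  expect_true(is.na(cm2$metrics[["spe"]]))
  expect_true(is.na(cm2$metrics[["apca"]]))
  expect_false(is.na(cm2$metrics[["sen"]]))
})

test_that("APCA equals the sensitivity/specificity mean on random predictions", {
  set.seed(12)
  for (i in 1:50) {
    pp <- data.frame(
      patient_id = sprintf("p%02d", 1:30),
      true_grade = sample(c("LGG", "HGG"), 30, replace = TRUE,
                          prob = c(0.3, 0.7)),
      predicted_grade = sample(c("LGG", "HGG"), 30, replace = TRUE),
      stringsAsFactors = FALSE)
    if (length(unique(pp$true_grade)) < 2) next
    cm <- confusion_and_metrics(pp)
    expect_equal(cm$metrics[["apca"]],
                 (cm$metrics[["sen"]] + cm$metrics[["spe"]]) / 2)
  }
})

random_scored_preds <- function(n = 40) {
  data.frame(patient_id = sprintf("p%02d", 1:n),
             true_grade = sample(c("LGG", "HGG"), n, replace = TRUE,
                                 prob = c(0.4, 0.6)),
             p_hgg = runif(n), stringsAsFactors = FALSE)
}

test_that("rank AUC agrees with the trapezoidal ROC area to 1e-12", {
  set.seed(77)
  for (i in 1:50) {
    pp <- random_scored_preds()
    if (length(unique(pp$true_grade)) < 2) next
    # inject ties occasionally
    if (i %% 3 == 0) pp$p_hgg <- round(pp$p_hgg, 1)
    ra <- roc_auc(pp)
    expect_equal(ra$auc, oracle_trapezoid_auc(ra$roc_points),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  pp <- random_scored_preds(60)
  base <- roc_auc(pp)$auc
  for (f in list(function(x) 3 * x + 2, function(x) x^3,
                 function(x) exp(x), function(x) atan(x))) {
    pp2 <- pp; pp2$p_hgg <- f(pp$p_hgg)
    expect_equal(roc_auc(pp2)$auc, base, tolerance = 1e-12)
  }
})

test_that("AUC extremes: separation gives 1, constant scores 0.5", {
  pp <- data.frame(patient_id = letters[1:6],
                   true_grade = rep(c("LGG", "HGG"), each = 3),
                   p_hgg = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(roc_auc(pp)$auc, 1)
  pp$p_hgg <- 0.5
  expect_equal(roc_auc(pp)$auc, 0.5)
  pp_one <- pp[pp$true_grade == "HGG", ]
  expect_error(roc_auc(pp_one), class = "undefined_auc_error")
})

test_that("rank AUC matches an established implementation on random data", {
  set.seed(31)
  for (i in 1:10) {
    pp <- random_scored_preds(50)
    if (length(unique(pp$true_grade)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(pp$true_grade, pp$p_hgg, levels = c("LGG", "HGG"),
                direction = "<"))))
    expect_equal(roc_auc(pp)$auc, ref, tolerance = 1e-12)
  }
})

test_that("the report is computed at patient level: slice order cannot change it", {
  set.seed(8)
  grades <- rep(c("LGG", "HGG"), 5)       # one grade per patient
  sp <- slice_df(rep(sprintf("p%02d", 1:10), each = 5),
                 rep(grades, each = 5),
                 runif(50))
  r1 <- metrics_report(aggregate_by_patient(sp))
  sh <- sp[sample(nrow(sp)), ]
  r2 <- metrics_report(aggregate_by_patient(sh))
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$confusion[order(names(r1$confusion))],
               r2$confusion[order(names(r2$confusion))])
})

test_that("ROC points are monotone nondecreasing in both coordinates", {
  set.seed(19)
  pp <- random_scored_preds(30)
  pts <- roc_auc(pp)$roc_points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(as.numeric(pts[1, ]), c(0, 0))
  expect_equal(as.numeric(pts[nrow(pts), ]), c(1, 1))
})
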