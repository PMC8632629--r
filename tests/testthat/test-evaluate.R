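test_that("patient-held-out folds are disjoint and leak-free", {
  pats <- rep(sprintf("P%02d", 1:19), each = 20)
  sp <- make_splits(pats, "patient_held_out", seed = 3)
  expect_equal(sp$n_folds, 5)
  # each patient tested in exactly one fold
  expect_equal(length(unique(sp$patient_folds)), 5)
  per_fold <- split(names(sp$patient_folds), sp$patient_folds)
  expect_equal(unname(sort(lengths(per_fold))), c(3, 4, 4, 4, 4))
  expect_equal(anyDuplicated(unlist(per_fold)), 0)
  # per-sample folds agree with the patient assignment
  expect_true(all(sp$fold == sp$patient_folds[pats]))
  # too few patients is a split error
  expect_error(make_splits(rep(c("a", "b", "c", "d"), 5),
                           "patient_held_out"), "split error")
})

test_that("patient-agnostic folds partition the samples", {
  sp <- make_splits(seq_len(1000), "patient_agnostic", seed = 4)
  expect_equal(sort(unique(sp$fold)), 1:5)
  expect_equal(length(sp$fold), 1000)
  expect_equal(as.numeric(table(sp$fold)), rep(200, 5))
})

test_that("confusion matrices count window-seconds and conserve totals", {
  lv <- class_levels()
  truth <- rep(lv, each = 30)
  # perfect classifier
  ev <- evaluate_predictions(truth, truth, lv)
  expect_equal(unname(diag(as.matrix(ev$confusion))), rep(30, 3))
  expect_equal(ev$misclassification_percent, 0)
  expect_equal(unname(ev$per_class_accuracy), rep(1, 3))
  # degenerate all-seizure classifier
  ev2 <- evaluate_predictions(truth, rep("seizure", 90), lv)
  expect_equal(ev2$overall_accuracy, 1 / 3)
  expect_equal(unname(ev2$confusion[, "seizure"]), rep(30, 3))
  # row sums = seconds per true class regardless of the model
  expect_equal(unname(rowSums(ev2$confusion)), rep(30, 3))
  # k-window samples count k seconds each
  ev6 <- evaluate_predictions(truth, truth, lv, k = 6)
  expect_equal(ev6$n_seconds, 90 * 6)
  # absent true classes are dropped, not zero-divided
  ev3 <- evaluate_predictions(rep("seizure", 10), rep("seizure", 10), lv)
  expect_equal(rownames(ev3$confusion), "seizure")
})

test_that("cross-validation reports pool folds without patient leakage", {
  set.seed(21)
  d <- 16
  pats <- rep(sprintf("P%d", 1:6), each = 30)
  mu <- matrix(rnorm(3 * d), 3)
  rownames(mu) <- class_levels()
  y <- sample(class_levels(), length(pats), replace = TRUE)
  x <- mu[y, ] + 0.3 * matrix(rnorm(length(pats) * d), length(pats))
  spec <- classifier_spec("shallow", 1, 3, d, seed = 1, epochs = 10,
                          batch_size = 32)
  rep_ <- run_cv(x, y, pats, spec, "patient_held_out", seed = 5)
  expect_length(rep_$folds, 5)
  expect_equal(sum(rep_$pooled$confusion), length(y))
  expect_gt(rep_$pooled$overall_accuracy, 0.9)
  # every sample tested exactly once
  expect_true(all(rep_$predictions$pred %in% class_levels()))
  # report serialization round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$mode, "patient_held_out")
  expect_equal(back$fold_mean_accuracy, rep_$fold_mean_accuracy)
})

test_that("scalp-category scoring rule selects the right windows", {
  # delayed seizures score only the surface-negative portion
  meta <- data.frame(
    state = c("seizure", "seizure", "seizure", "pre_seizure"),
    scalp_category = c("delayed", "delayed", "surface_negative",
                       "delayed"),
    start = c(700, 705, 700, 690),
    scalp_onset_s = c(705, 705, NA, 705))
  m <- szgraph:::ictal_scored_mask(meta)
  expect_equal(m, c(TRUE, FALSE, TRUE, FALSE))
  # a delayed seizure with scalp onset equal to iEEG onset scores zero
  meta2 <- data.frame(state = "seizure", scalp_category = "delayed",
                      start = 700, scalp_onset_s = 700)
  expect_false(any(szgraph:::ictal_scored_mask(meta2)))
})

test_that("lateralization report handles single-side datasets", {
  set.seed(31)
  d <- 16
  lv <- class_levels("four_class")
  mu <- matrix(rnorm(4 * d), 4)
  rownames(mu) <- lv
  y <- sample(lv, 160, replace = TRUE)
  x <- mu[y, ] + 0.2 * matrix(rnorm(160 * d), 160)
  spec <- classifier_spec("shallow", 1, 4, d, seed = 2, epochs = 12,
                          batch_size = 32)
  m <- train_classifier(spec, x, y)
  right_only <- y %in% c("seizure_right")
  meta <- data.frame(state = ifelse(right_only, "seizure", "non_seizure"),
                     side = "right", scalp_category = "simultaneous",
                     start = seq_along(y), scalp_onset_s = NA_real_)
  la <- lateralization_analysis(m, x, meta)
  expect_named(la$by_side, "right")
  expect_true(is.na(la$cross_confusion))
  expect_gt(la$by_side$right$detection_rate, 0.8)
})
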