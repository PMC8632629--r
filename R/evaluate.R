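#' Build a 5-fold split plan
#'
#' Two designs:
#' * `patient_held_out` - folds partition patients; every sample of a
#'   patient is tested in exactly one fold and never trained on in that
#'   fold.  With 19 patients the shuffled assignment yields five
#'   pairwise-disjoint test groups of 4/4/4/4/3 patients (five disjoint
#'   triples plus the four remaining patients spread one per fold).
#' * `patient_agnostic` - samples are shuffled individually into folds
#'   (bag-of-epochs); every sample is tested exactly once.
#'
#' @param patients character/integer patient id per sample.
#' @param mode `"patient_held_out"` or `"patient_agnostic"`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return A `szg_splits`: `fold` (test-fold index per sample), `mode`,
#'   `n_folds`, and for the patient design `patient_folds`.
#' @export
make_splits <- function(patients,
                        mode = c("patient_held_out", "patient_agnostic"),
                        n_folds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  n <- length(patients)
  set.seed(as.integer(seed))
  if (mode == "patient_agnostic") {
    if (n < n_folds) stop("split error: fewer samples than folds")
    fold <- sample(rep_len(seq_len(n_folds), n))
    return(structure(list(mode = mode, n_folds = n_folds, fold = fold,
                          patient_folds = NULL, seed = seed),
                     class = "szg_splits"))
  }
  up <- unique(patients)
  if (length(up) < n_folds)
    stop("split error: patient_held_out requires at least ", n_folds,
         " patients")
  shuf <- sample(up)
  # round-robin over the shuffled patient order
  pf <- integer(length(up))
  pf[match(shuf, up)] <- rep_len(seq_len(n_folds), length(up))
  fold <- pf[match(patients, up)]
  structure(list(mode = mode, n_folds = n_folds, fold = fold,
                 patient_folds = stats::setNames(pf, up), seed = seed),
            class = "szg_splits")
}

#' Confusion matrix and accuracies for one set of predictions
#'
#' Counts are in window-seconds: a sample stacking `k` windows
#' contributes `k` seconds to its cell.  True classes absent from the
#' test set are reported as absent (dropped rows), not zero-divided.
#'
#' @param truth,pred character labels.
#' @param levels class ordering (see [class_levels()]).
#' @param k windows per sample.
#' @return A `szg_eval`: `confusion` (rows = truth), `per_class_accuracy`,
#'   `overall_accuracy`, `misclassification_percent`, `n_seconds`.
#' @export
evaluate_predictions <- function(truth, pred, levels, k = 1L) {
  stopifnot(length(truth) == length(pred))
  cm <- table(factor(truth, levels = levels),
              factor(pred, levels = levels)) * k
  present <- rowSums(cm) > 0
  cm <- cm[present, , drop = FALSE]
  acc_pc <- diag(as.matrix(cm[, rownames(cm), drop = FALSE])) / rowSums(cm)
  overall <- sum(vapply(rownames(cm), function(l) cm[l, l], 0)) / sum(cm)
  structure(list(confusion = cm,
                 per_class_accuracy = acc_pc,
                 overall_accuracy = overall,
                 misclassification_percent = 100 * (1 - overall),
                 n_seconds = sum(cm)),
            class = "szg_eval")
}

#' @export
print.szg_eval <- function(x, ...) {
  cat("<szg_eval> confusion (window-seconds):\n")
  print(x$confusion)
  cat(sprintf("overall accuracy %.4f, misclassification %.2f%%\n",
              x$overall_accuracy, x$misclassification_percent))
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' Trains one classifier per fold on the complementary folds and
#' evaluates on the held-out fold; reports per-fold and pooled
#' confusion matrices and accuracies.
#'
#' @param x sample matrix (N x k*input_dim).
#' @param y labels.
#' @param patients patient id per sample.
#' @param spec a `szg_spec`.
#' @param mode split design, see [make_splits()].
#' @param seed seed for the split plan.
#' @return A `szg_report`: `folds` (list of `szg_eval`), `pooled`
#'   (`szg_eval` over all held-out predictions), `fold_mean_accuracy`,
#'   `splits`, `predictions` (pooled data frame with truth, prediction,
#'   fold and sample index).
#' @export
run_cv <- function(x, y, patients, spec,
                   mode = c("patient_held_out", "patient_agnostic"),
                   seed = 1L) {
  mode <- match.arg(mode)
  levels_ <- class_levels(if (spec$n_classes == 3L) "three_class"
                          else "four_class")
  splits <- make_splits(patients, mode, seed = seed)
  folds <- vector("list", splits$n_folds)
  pred_all <- character(length(y))
  for (f in seq_len(splits$n_folds)) {
    tr <- splits$fold != f
    te <- !tr
    if (any(patients[tr] %in% patients[te]) && mode == "patient_held_out")
      stop("split error: patient leakage across the fold boundary")
    model <- train_classifier(build_classifier(spec),
                              x[tr, , drop = FALSE], y[tr])
    pr <- predict_classifier(model, x[te, , drop = FALSE])
    pred_all[te] <- pr$class
    folds[[f]] <- evaluate_predictions(y[te], pr$class, levels_, spec$k)
  }
  pooled <- evaluate_predictions(y, pred_all, levels_, spec$k)
  structure(list(folds = folds, pooled = pooled,
                 fold_mean_accuracy =
                   mean(vapply(folds, `[[`, 0, "overall_accuracy")),
                 splits = splits,
                 predictions = data.frame(truth = y, pred = pred_all,
                                          fold = splits$fold,
                                          patient = patients,
                                          stringsAsFactors = FALSE)),
            class = "szg_report")
}

#' @export
print.szg_report <- function(x, ...) {
  cat(sprintf("<szg_report> %s, %d folds\n", x$splits$mode,
              x$splits$n_folds))
  print(x$pooled)
  cat(sprintf("fold-mean accuracy %.4f\n", x$fold_mean_accuracy))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report a `szg_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  obj <- list(
    mode = report$splits$mode,
    n_folds = report$splits$n_folds,
    pooled = list(confusion = as.data.frame.matrix(report$pooled$confusion),
                  per_class_accuracy =
                    as.list(report$pooled$per_class_accuracy),
                  overall_accuracy = report$pooled$overall_accuracy,
                  misclassification_percent =
                    report$pooled$misclassification_percent),
    fold_mean_accuracy = report$fold_mean_accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

ictal_scored_mask <- function(meta) {
  # which ictal samples enter the scalp-detection analyses:
  # surface_negative & simultaneous -> all ictal windows;
  # delayed -> only [iEEG onset, scalp onset)
  ict <- meta$state == "seizure"
  scored <- ict
  del <- ict & meta$scalp_category == "delayed"
  scored[del] <- meta$start[del] + 1 <= meta$scalp_onset_s[del]
  scored
}

#' Detection of scalp-invisible seizure activity, per scalp category
#'
#' Scores a scalp-view model on ictal windows: for surface-negative and
#' simultaneous seizures all ictal windows, for delayed-onset seizures
#' only the surface-negative portion (windows in
#' `[iEEG onset, scalp onset)`).  Reports the fraction of scored
#' windows classified as seizure (any seizure class), per category.
#'
#' @param model trained scalp-view classifier.
#' @param x sample matrix aligned with `meta`.
#' @param meta data frame with `state`, `scalp_category`, `start`,
#'   `scalp_onset_s` per sample (see [build_dataset()]).
#' @return A `szg_surfneg` list: per-category `detection_rate` and
#'   `n_seconds`, plus the misclassification split of missed windows.
#' @export
surface_negative_analysis <- function(model, x, meta) {
  scored <- ictal_scored_mask(meta)
  cats <- intersect(c("surface_negative", "delayed", "simultaneous"),
                    unique(meta$scalp_category[scored]))
  pr <- if (any(scored))
    predict_classifier(model, x[scored, , drop = FALSE])$class
  else character(0)
  sub <- meta[scored, , drop = FALSE]
  is_sz <- pr %in% c("seizure", "seizure_left", "seizure_right")
  out <- lapply(cats, function(cc) {
    m <- sub$scalp_category == cc
    list(detection_rate = mean(is_sz[m]),
         n_seconds = sum(m),
         missed_as = table(factor(pr[m & !is_sz],
                                  levels = model$classes)))
  })
  names(out) <- cats
  structure(list(by_category = out,
                 predictions = data.frame(category = sub$scalp_category,
                                          pred = pr,
                                          stringsAsFactors = FALSE)),
            class = "szg_surfneg")
}

#' Left/right lateralization analysis of a 4-class model
#'
#' Per-side, per-scalp-category detection rates on scored ictal windows
#' (see [surface_negative_analysis()] for the scoring rule) and the
#' left/right cross-lateralization confusion count.  With a single-side
#' dataset the cross-confusion is reported as `NA` (not applicable).
#'
#' @param model trained 4-class classifier.
#' @param x sample matrix aligned with `meta`.
#' @param meta data frame with `state`, `side`, `scalp_category`,
#'   `start`, `scalp_onset_s`.
#' @return A `szg_lateral` list: `by_side` (nested per-category rates),
#'   `cross_confusion` (seconds of left predicted right + right
#'   predicted left, or `NA`).
#' @export
lateralization_analysis <- function(model, x, meta) {
  stopifnot(model$spec$n_classes == 4L)
  scored <- ictal_scored_mask(meta)
  sub <- meta[scored, , drop = FALSE]
  pr <- if (any(scored))
    predict_classifier(model, x[scored, , drop = FALSE])$class
  else character(0)
  sides <- intersect(c("left", "right"), unique(sub$side))
  by_side <- lapply(sides, function(s) {
    m <- sub$side == s
    cats <- unique(sub$scalp_category[m])
    per_cat <- lapply(cats, function(cc) {
      mm <- m & sub$scalp_category == cc
      list(detection_rate = mean(pr[mm] == paste0("seizure_", s)),
           n_seconds = sum(mm))
    })
    names(per_cat) <- cats
    list(per_category = per_cat,
         detection_rate = mean(pr[m] == paste0("seizure_", s)),
         opposite_seconds = sum(pr[m] == paste0("seizure_",
                                                setdiff(c("left", "right"),
                                                        s))))
  })
  names(by_side) <- sides
  cross <- if (length(sides) == 2L)
    sum(vapply(by_side, `[[`, 0, "opposite_seconds"))
  else NA_real_
  structure(list(by_side = by_side, cross_confusion = cross),
            class = "szg_lateral")
}
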