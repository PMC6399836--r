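#' Confusion matrix of window decisions
#'
#' Rows are actual classes, columns predicted. `row_percent` normalizes
#' each row to 100; the per-class accuracy is its diagonal and the overall
#' accuracy the unweighted mean of the per-class accuracies (the
#' class-balanced convention). Classes with no actual windows are flagged
#' in `empty_classes` and carry `NA` rows rather than silent zeros.
#'
#' @param actual,predicted Equal-length label vectors drawn from
#'   `classes`.
#' @param classes Class order for rows/columns (default [class_order()]).
#' @return An object of class `"confusion_matrix"`: list with `classes`,
#'   `counts` (K x K integer), `row_percent`, `per_class_accuracy`,
#'   `overall_accuracy` and `empty_classes`.
#' @examples
#' cm <- confusion_matrix(c("AB", "AB", "ER"), c("AB", "ER", "ER"),
#'                        classes = c("AB", "ER"))
#' cm$per_class_accuracy
#' @export
confusion_matrix <- function(actual, predicted, classes = class_order()) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  counts <- table(factor(actual, classes), factor(predicted, classes))
  counts <- matrix(as.integer(counts), length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  row_percent <- counts / ifelse(rs > 0, rs, NA_real_) * 100
  per_class <- diag(row_percent)
  names(per_class) <- classes
  structure(list(classes = classes, counts = counts,
                 row_percent = row_percent,
                 per_class_accuracy = per_class,
                 overall_accuracy = mean(per_class, na.rm = TRUE),
                 empty_classes = classes[rs == 0]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 0, ...) {
  cat("Confusion matrix (row % of actual-class windows, rounded):\n")
  print(round(x$row_percent, digits))
  cat("Overall accuracy (mean of class accuracies):",
      round(x$overall_accuracy, 1), "%\n")
  if (length(x$empty_classes)) {
    cat("Classes with no test windows:",
        paste(x$empty_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Trial-wise leave-one-out cross-validation
#'
#' With three retained trials per class, each combination of two trials
#' (of every class) trains a classifier that is tested on the held-out
#' third: fold j trains on within-class trials ranked != j and tests on
#' rank j. Holding out whole trials avoids leakage between temporally
#' overlapping windows. Per-class accuracies are computed within each fold
#' and averaged across the three folds; pooled window counts over all
#' folds are also retained.
#'
#' @param trial_features List of `"feature_matrix"` objects, one per
#'   retained trial, each carrying a single class label and trial id;
#'   exactly 3 trials per class are required and every trial must
#'   contribute at least one window.
#' @param prior,lambda Passed to [fit_lda()].
#' @param classes Class order for reporting.
#' @return An object of class `"loocv_result"`: list with `folds` (data
#'   frame of `actual`, `predicted`, `fold`, `trial_id`), `fold_class_acc`
#'   (folds x classes matrix of within-fold per-class accuracies),
#'   `per_class_accuracy` (fold-averaged), `overall_accuracy` (mean of the
#'   class accuracies), and `confusion` (pooled [confusion_matrix()]).
#' @export
loocv_trialwise <- function(trial_features, prior = NULL, lambda = NULL,
                            classes = class_order()) {
  labs <- vapply(trial_features, function(f) unique(f$labels)[1L], "")
  ids <- vapply(trial_features, function(f) unique(f$trial_ids)[1L], "")
  if (any(table(labs) != 3L) || !setequal(unique(labs), classes)) {
    stop("need exactly 3 retained trials for each class")
  }
  nwin <- vapply(trial_features, function(f) nrow(f$values), 0L)
  if (any(nwin == 0L)) {
    stop("trial(s) with no analysis windows: ",
         paste(ids[nwin == 0L], collapse = ", "))
  }
  rank_in_class <- stats::ave(seq_along(labs), labs, FUN = seq_along)
  res <- list()
  fold_acc <- matrix(NA_real_, 3L, length(classes),
                     dimnames = list(NULL, classes))
  for (j in 1:3) {
    train <- rbind_features(trial_features[rank_in_class != j])
    test <- rbind_features(trial_features[rank_in_class == j])
    model <- fit_lda(train$values, train$labels, prior = prior,
                     lambda = lambda)
    pred <- predict(model, test$values)
    res[[j]] <- data.frame(actual = test$labels, predicted = pred,
                           fold = j, trial_id = test$trial_ids,
                           stringsAsFactors = FALSE)
    for (cl in classes) {
      sel <- test$labels == cl
      if (any(sel)) fold_acc[j, cl] <- 100 * mean(pred[sel] == cl)
    }
  }
  folds <- do.call(rbind, res)
  per_class <- colMeans(fold_acc)
  structure(list(folds = folds, fold_class_acc = fold_acc,
                 per_class_accuracy = per_class,
                 overall_accuracy = mean(per_class),
                 confusion = confusion_matrix(folds$actual, folds$predicted,
                                              classes)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("Trial-wise LOOCV over", nrow(x$folds), "test windows, 3 folds\n")
  cat("Per-class accuracy (%, fold-averaged):\n")
  print(round(x$per_class_accuracy, 1))
  cat("Overall:", round(x$overall_accuracy, 1), "%\n")
  invisible(x)
}

#' Cohort accuracy summary across feature sets
#'
#' Per-class accuracy is averaged over participants for each feature set;
#' an `Average` row averages the eight class accuracies. Cells at or above
#' 90% (a commonly used usability threshold for myoelectric control) are
#' flagged.
#'
#' @param participant_results List of [evaluate_participant()] results (or
#'   any list of lists mapping feature-set name to a `"loocv_result"`).
#' @param feature_sets Feature sets (columns) to include.
#' @return An object of class `"accuracy_summary"`: list with `table`
#'   ((8+1) x n_sets matrix of accuracies), `flagged` (logical matrix,
#'   `>= 90`), and `n_participants`.
#' @export
summarize_feature_sets <- function(participant_results,
                                   feature_sets = c("EMG_TD", "TORQUE",
                                                    "LOADCELL", "EMG_LC")) {
  classes <- class_order()
  tab <- matrix(NA_real_, length(classes) + 1L, length(feature_sets),
                dimnames = list(c(classes, "Average"), feature_sets))
  for (fs in feature_sets) {
    acc <- sapply(participant_results, function(p) {
      r <- p$loocv[[fs]]
      if (is.null(r)) stop("missing feature-set result: ", fs)
      r$per_class_accuracy[classes]
    })
    acc <- matrix(acc, length(classes))
    tab[classes, fs] <- rowMeans(acc)
    tab["Average", fs] <- mean(tab[classes, fs])
  }
  structure(list(table = tab, flagged = tab >= 90,
                 n_participants = length(participant_results)),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("Classification accuracy (%) averaged over",
      x$n_participants, "participants\n")
  disp <- matrix(paste0(format(round(x$table), width = 3),
                        ifelse(x$flagged, "*", " ")),
                 nrow(x$table), dimnames = dimnames(x$table))
  print(disp, quote = FALSE)
  cat("* cell >= 90% accuracy\n")
  invisible(x)
}

#' Normalized abduction/adduction vs rotation torque scatter
#'
#' For each analysis window of the AB, AD, ER and IR trials, pairs the
#' window-mean abduction/adduction torque with the window-mean
#' external/internal rotation torque, each normalized by the MVT of the
#' direction matching its sign (positive values by the AB or ER MVT,
#' negative by AD or IR). Overlap between the AB and ER (and AD and IR)
#' clouds visualizes coupled task strategies.
#'
#' @param window_torques Data frame with numeric columns `abad` and `erir`
#'   (window-mean torques, N m) and a `class` column.
#' @param mvts Named numeric vector with positive entries `AB`, `AD`,
#'   `ER`, `IR` (N m).
#' @return The input data frame with added columns `abad_norm` and
#'   `erir_norm`.
#' @export
torque_space_scatter <- function(window_torques, mvts) {
  need <- c("AB", "AD", "ER", "IR")
  if (!all(need %in% names(mvts))) {
    stop("mvts must contain entries AB, AD, ER, IR")
  }
  if (any(!is.finite(mvts[need])) || any(mvts[need] <= 0)) {
    stop("MVTs must be positive")
  }
  stopifnot(all(c("abad", "erir", "class") %in% names(window_torques)))
  wt <- window_torques
  wt$abad_norm <- ifelse(wt$abad >= 0, wt$abad / mvts["AB"],
                         wt$abad / mvts["AD"])
  wt$erir_norm <- ifelse(wt$erir >= 0, wt$erir / mvts["ER"],
                         wt$erir / mvts["IR"])
  wt
}

#' Spearman rank correlation with t-approximated p-value
#'
#' Rank correlation between per-participant classification accuracies and
#' an ordinal clinical score: Pearson correlation of average ranks, with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (approximate for small n).
#'
#' @param x,y Paired finite numeric vectors, length >= 3.
#' @return List with `rho`, `p_value` and `n`.
#' @examples
#' spearman_correlation(1:5, c(3, 1, 2, 5, 4))   # rho = 0.6
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero-variance ranks: correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
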