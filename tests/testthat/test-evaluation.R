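# minimal feature_matrix construction for evaluation-level tests
fake_features <- function(label, trial_id, center, n = 12, D = 2, sd = 0.05,
                          feature_set = "TORQUE") {
  vals <- matrix(rnorm(n * D, sd = sd), n, D)
  vals <- sweep(vals, 2, center, "+")
  structure(list(values = vals, labels = rep(label, n),
                 trial_ids = rep(trial_id, n), feature_set = feature_set,
                 feature_names = paste0("f", seq_len(D))),
            class = "feature_matrix")
}

# well-separated 8-class toy problem: 3 trials per class, class centres on
# a wide grid
toy_trials <- function(sd = 0.05, seed = 19) {
  set.seed(seed)
  classes <- class_order()
  centers <- cbind(10 * (1:8), -10 * (1:8))
  out <- list()
  for (i in seq_along(classes)) {
    for (k in 1:3) {
      out[[paste(classes[i], k, sep = "_")]] <-
        fake_features(classes[i], paste(classes[i], k, sep = "_"),
                      centers[i, ], sd = sd)
    }
  }
  out
}

test_that("confusion matrix counts, percentages and accuracies are consistent", {
  cm <- confusion_matrix(rep("AB", 10), c(rep("AB", 9), "ER"))
  expect_equal(cm$counts["AB", "AB"], 9L)
  expect_equal(cm$row_percent["AB", "AB"], 90)
  expect_equal(cm$row_percent["AB", "ER"], 10)
  # identity case
  labs <- rep(class_order(), each = 5)
  cmi <- confusion_matrix(labs, labs)
  expect_equal(unname(cmi$per_class_accuracy), rep(100, 8))
  expect_equal(cmi$overall_accuracy, 100)
  # rows with data sum to 100 exactly
  expect_true(all(abs(rowSums(cm$row_percent, na.rm = TRUE)[
    rowSums(cm$counts) > 0] - 100) < 1e-9))
  # empty actual classes are flagged, not silently zeroed
  expect_setequal(cm$empty_classes, setdiff(class_order(), "AB"))
  expect_true(all(is.na(cm$row_percent["EF", ])))
  expect_error(confusion_matrix("AB", "XX"), "unknown labels")
  expect_error(confusion_matrix(c("AB", "ER"), "AB"), "equal length")
})

test_that("a stub classifier that always answers EF yields the counting oracle", {
  actual <- rep(class_order(), each = 10)
  predicted <- rep("EF", length(actual))
  cm <- confusion_matrix(actual, predicted)
  expect_equal(unname(cm$per_class_accuracy["EF"]), 100)
  expect_equal(unname(cm$per_class_accuracy[setdiff(class_order(), "EF")]),
               rep(0, 7))
  expect_equal(cm$overall_accuracy, 12.5)
})

test_that("trial-wise LOOCV folds partition the trials correctly", {
  res <- loocv_trialwise(toy_trials())
  # every trial tested exactly once across the 3 folds
  tested <- unique(res$folds[, c("trial_id", "fold")])
  expect_equal(nrow(tested), 24)
  expect_equal(unname(table(tested$fold)), rep(8L, 3), ignore_attr = TRUE)
  # fold j tests within-class trial j (trains on the other two)
  expect_true(all(sub(".*_", "", tested$trial_id) == tested$fold))
  # window counts conserved into the pooled confusion matrix
  expect_equal(sum(res$confusion$counts), nrow(res$folds))
  expect_equal(nrow(res$folds), 24 * 12)
  # separable problem: perfect accuracy
  expect_equal(res$overall_accuracy, 100)
  expect_equal(unname(res$per_class_accuracy), rep(100, 8))
})

test_that("per-class accuracies average over folds, overall over classes", {
  res <- loocv_trialwise(toy_trials(sd = 40, seed = 23))  # noisy, imperfect
  expect_true(all(res$per_class_accuracy >= 0 & res$per_class_accuracy <= 100))
  expect_equal(unname(res$per_class_accuracy),
               unname(colMeans(res$fold_class_acc)))
  expect_equal(res$overall_accuracy, mean(res$per_class_accuracy))
  expect_true(res$overall_accuracy < 100)
})

test_that("LOOCV rejects malformed trial sets", {
  tt <- toy_trials()
  expect_error(loocv_trialwise(tt[-1]), "exactly 3")
  tt[[1]]$values <- tt[[1]]$values[0, , drop = FALSE]
  tt[[1]]$labels <- character(0)
  tt[[1]]$trial_ids <- character(0)
  expect_error(loocv_trialwise(tt), "exactly 3|no analysis windows")
})

test_that("feature-set summary averages participants and flags >= 90%", {
  mk <- function(accs) {
    pc <- accs; names(pc) <- class_order()
    list(loocv = list(TORQUE = list(per_class_accuracy = pc,
                                    overall_accuracy = mean(pc))))
  }
  one <- summarize_feature_sets(list(mk(rep(80, 8))), "TORQUE")
  expect_equal(unname(one$table[, "TORQUE"]), rep(80, 9))
  two <- summarize_feature_sets(list(mk(rep(80, 8)), mk(rep(100, 8))),
                                "TORQUE")
  expect_equal(unname(two$table["Average", "TORQUE"]), 90)
  expect_true(all(two$flagged))     # 90 is flagged (>= 90)
  expect_error(summarize_feature_sets(list(mk(rep(80, 8))), "EMG_TD"),
               "missing feature-set")
})

test_that("torque scatter normalizes by the MVT matching each sign", {
  wt <- data.frame(abad = c(10, -8, 1), erir = c(2, -6, 9),
                   class = c("AB", "AD", "ER"))
  mvts <- c(AB = 10, AD = 16, ER = 18, IR = 12)
  sc <- torque_space_scatter(wt, mvts)
  expect_equal(sc$abad_norm, c(1, -0.5, 0.1))
  expect_equal(sc$erir_norm, c(2 / 18, -0.5, 0.5))
  expect_error(torque_space_scatter(wt, c(AB = 0, AD = 1, ER = 1, IR = 1)),
               "positive")
})

test_that("Spearman correlation matches hand ranks and the reference", {
  expect_equal(spearman_correlation(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1)
  r <- spearman_correlation(1:5, c(3, 1, 2, 5, 4))
  expect_equal(r$rho, 0.6)
  # cross-check rho against the established implementation
  set.seed(43)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(spearman_correlation(x, y)$rho,
               unname(cor(x, y, method = "spearman")))
  # t-approximation p-value against cor.test's asymptotic option
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(sign(spearman_correlation(x, y)$rho), sign(unname(ct$estimate)))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  expect_error(spearman_correlation(rep(1, 5), 1:5), "zero-variance")
})

test_that("load-cell features beat overlapping EMG, and fusion beats load cell", {
  # torque directions fully separable, EMG activation rows almost identical
  res <- eval_coupling_cohort(
    0, c("EMG_TD", "LOADCELL", "EMG_LC"), n = 1, seed = 401,
    label = "overlapping", activation_matrix = overlapping_activation())
  tab <- res$summary$table["Average", ]
  expect_gt(tab["LOADCELL"], tab["EMG_TD"] + 5)
  expect_gte(tab["EMG_LC"], tab["LOADCELL"] - 1)
})
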