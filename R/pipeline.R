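#' Preprocess one trial
#'
#' Notch-filters the EMG channels, converts the load-cell channels to
#' joint torques, rectifies the primary-axis torque toward the tested
#' direction, and computes the trial MVT from its 200 ms moving average.
#'
#' @param trial A `"trial_recording"`.
#' @param geometry A [rigid_body_geometry()].
#' @param window_ms Moving-average window for the MVT (ms).
#' @param ... Passed to [notch_filter()].
#' @return The trial with added elements `emg_filtered`, `torques`,
#'   `primary` and `mvt`.
#' @export
preprocess_trial <- function(trial, geometry = rigid_body_geometry(),
                             window_ms = 200, ...) {
  stopifnot(inherits(trial, "trial_recording"))
  emg_f <- apply(trial$emg, 2L, notch_filter, fs = trial$fs, ...)
  torques <- compute_joint_torques(trial$loadcell, geometry, fs = trial$fs)
  primary <- primary_torque(torques, trial$class)
  mvt <- max_voluntary_torque(primary, trial$fs, window_ms = window_ms)
  trial$emg_filtered <- emg_f
  trial$torques <- torques
  trial$primary <- primary
  trial$mvt <- mvt$mvt
  trial
}

#' Evaluate one participant with trial-wise LOOCV
#'
#' Runs the full offline analysis for one participant: preprocess every
#' trial, retain the three largest-MVT trials per direction, segment each
#' retained trial where its rectified primary torque exceeds 20% of the
#' trial MVT, extract the requested feature-set variants from identical
#' window partitions, and cross-validate a pooled-covariance LDA
#' classifier trial-wise. Also returns the normalized AB/AD-vs-ER/IR
#' torque scatter used to inspect coupled task strategies.
#'
#' @param trials List of `"trial_recording"` objects for one participant
#'   (at least 3 per class, in acquisition order).
#' @param geometry A [rigid_body_geometry()].
#' @param feature_sets Character vector of feature-set variants to run.
#' @param window_ms,increment_ms Analysis window and decision increment
#'   (ms).
#' @param threshold Segmentation threshold as a fraction of MVT.
#' @param deadband Deadband for the zero-crossing / slope-sign-change
#'   counts.
#' @param prior,lambda Passed to [fit_lda()].
#' @return An object of class `"participant_result"`: list with
#'   `participant_id`, `loocv` (named list of `"loocv_result"`),
#'   `selection` (per-class retained indices and stop-criterion flags),
#'   `mvts` (per-class direction MVTs over retained trials), `scatter`
#'   (from [torque_space_scatter()]), and `clinical`.
#' @export
evaluate_participant <- function(trials,
                                 geometry = rigid_body_geometry(),
                                 feature_sets = c("EMG_TD", "TORQUE",
                                                  "LOADCELL", "EMG_LC"),
                                 window_ms = 200, increment_ms = 25,
                                 threshold = 0.20, deadband = 0,
                                 prior = NULL, lambda = NULL) {
  stopifnot(length(trials) > 0L)
  pid <- trials[[1L]]$participant_id
  pp <- lapply(trials, preprocess_trial, geometry = geometry,
               window_ms = window_ms)
  labs <- vapply(pp, `[[`, "", "class")
  classes <- class_order()
  retained <- list()
  selection <- list()
  for (cl in classes) {
    idx <- which(labs == cl)
    if (length(idx) < 3L) {
      stop("participant ", pid, " has ", length(idx), " trials of class ",
           cl, " (need >= 3)")
    }
    sel <- select_trials(vapply(pp[idx], `[[`, 0, "mvt"))
    selection[[cl]] <- sel
    retained[[cl]] <- pp[idx[sel$selected]]
  }
  mvts <- vapply(retained, function(tr) max(vapply(tr, `[[`, 0, "mvt")), 0)
  names(mvts) <- classes
  # identical window partitions across feature sets: segment once per trial
  seg_trials <- lapply(unlist(retained, recursive = FALSE), function(tr) {
    tr$segments <- segment_active(tr$primary, tr$mvt, threshold = threshold)
    tr
  })
  for (i in seq_along(seg_trials)) {
    if (is.null(seg_trials[[i]]$trial_id)) {
      seg_trials[[i]]$trial_id <-
        sprintf("%s_%s_%d", pid, seg_trials[[i]]$class, i)
    }
  }
  feats_of <- function(tr, fs_name) {
    extract_features(tr$emg_filtered, tr$loadcell, tr$torques$torque,
                     tr$segments, fs_name, fs = tr$fs,
                     window_ms = window_ms, increment_ms = increment_ms,
                     deadband = deadband, label = tr$class,
                     trial_id = tr$trial_id)
  }
  loocv <- list()
  for (fs_name in feature_sets) {
    tf <- lapply(seg_trials, feats_of, fs_name = fs_name)
    loocv[[fs_name]] <- loocv_trialwise(tf, prior = prior, lambda = lambda,
                                        classes = classes)
  }
  # window-mean torques of the four rotation/ab-adduction classes
  scatter <- NULL
  sc_trials <- seg_trials[vapply(seg_trials, `[[`, "", "class") %in%
                            c("AB", "AD", "ER", "IR")]
  if (length(sc_trials) && all(c("AB", "AD", "ER", "IR") %in% names(mvts))) {
    rows <- lapply(sc_trials, function(tr) {
      f <- extract_features(tr$emg_filtered, tr$loadcell, tr$torques$torque,
                            tr$segments, "TORQUE", fs = tr$fs,
                            window_ms = window_ms,
                            increment_ms = increment_ms,
                            label = tr$class)
      if (nrow(f$values) == 0L) return(NULL)
      data.frame(abad = f$values[, "abad_mean"],
                 erir = f$values[, "erir_mean"],
                 class = tr$class, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows)) {
      scatter <- torque_space_scatter(rows, mvts[c("AB", "AD", "ER", "IR")])
    }
  }
  structure(list(participant_id = pid, loocv = loocv, selection = selection,
                 mvts = mvts, scatter = scatter,
                 clinical = trials[[1L]]$clinical),
            class = "participant_result")
}

#' @export
print.participant_result <- function(x, ...) {
  cat("Participant", x$participant_id, "- feature sets:",
      paste(names(x$loocv), collapse = ", "), "\n")
  for (fs in names(x$loocv)) {
    cat(sprintf("  %-8s overall %.1f%%\n", fs,
                x$loocv[[fs]]$overall_accuracy))
  }
  invisible(x)
}

#' Evaluate a whole cohort
#'
#' Runs [evaluate_participant()] for every participant in a dataset,
#' skipping (with a warning) participants with insufficient trials,
#' summarizes accuracies across feature sets, averages the per-participant
#' confusion matrices, and rank-correlates per-participant accuracy with
#' the available clinical scores.
#'
#' @param dataset A `"trial_dataset"` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param feature_sets Feature-set variants to evaluate.
#' @param correlate_set Feature set whose overall accuracy is correlated
#'   with the clinical scores.
#' @param ... Passed to [evaluate_participant()].
#' @return An object of class `"cohort_result"`: list with `participants`
#'   (list of `"participant_result"`), `summary` (an
#'   `"accuracy_summary"`), `confusions` (per-feature-set cohort-mean
#'   `row_percent` matrices), `correlations` (list of
#'   [spearman_correlation()] results, or NULL when fewer than 3
#'   participants), and `skipped` (ids of skipped participants).
#' @export
evaluate_cohort <- function(dataset,
                            feature_sets = c("EMG_TD", "TORQUE",
                                             "LOADCELL", "EMG_LC"),
                            correlate_set = "LOADCELL", ...) {
  stopifnot(inherits(dataset, "trial_dataset"))
  pids <- unique(vapply(dataset$trials, `[[`, "", "participant_id"))
  results <- list()
  skipped <- character(0)
  for (pid in pids) {
    tr <- dataset$trials[vapply(dataset$trials, `[[`, "",
                                "participant_id") == pid]
    res <- tryCatch(
      evaluate_participant(tr, geometry = dataset$config$geometry,
                           feature_sets = feature_sets, ...),
      error = function(e) {
        warning("skipping participant ", pid, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) skipped <- c(skipped, pid) else results[[pid]] <- res
  }
  if (!length(results)) stop("no participant could be evaluated")
  summary <- summarize_feature_sets(results, feature_sets)
  confusions <- lapply(feature_sets, function(fs) {
    mats <- lapply(results, function(p) p$loocv[[fs]]$confusion$row_percent)
    Reduce(`+`, mats) / length(mats)
  })
  names(confusions) <- feature_sets
  correlations <- NULL
  if (length(results) >= 3L && correlate_set %in% feature_sets) {
    acc <- vapply(results, function(p)
      p$loocv[[correlate_set]]$overall_accuracy, 0)
    fma <- vapply(results, function(p)
      if (is.null(p$clinical)) NA_real_ else p$clinical$ue_fma, 0)
    reach <- vapply(results, function(p)
      if (is.null(p$clinical)) NA_real_ else p$clinical$reach, 0)
    # constant accuracies (e.g. everyone at 100%) leave the rank
    # correlation undefined; report NA rather than failing the run
    safe_cor <- function(x, y) {
      tryCatch(spearman_correlation(x, y), error = function(e) {
        list(rho = NA_real_, p_value = NA_real_, n = length(x),
             note = conditionMessage(e))
      })
    }
    correlations <- list()
    if (all(is.finite(fma))) correlations$ue_fma <- safe_cor(acc, fma)
    if (all(is.finite(reach))) correlations$reach <- safe_cor(acc, reach)
  }
  structure(list(participants = results, summary = summary,
                 confusions = confusions, correlations = correlations,
                 skipped = skipped),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  print(x$summary)
  if (length(x$skipped)) {
    cat("Skipped participants:", paste(x$skipped, collapse = ", "), "\n")
  }
  if (!is.null(x$correlations)) {
    for (nm in names(x$correlations)) {
      cc <- x$correlations[[nm]]
      if (is.na(cc$rho)) {
        cat(sprintf("Spearman accuracy vs %s: undefined (%s)\n", nm,
                    cc$note))
      } else {
        cat(sprintf("Spearman accuracy vs %s: rho = %.3f, p = %.3f (n = %d)\n",
                    nm, cc$rho, cc$p_value, cc$n))
      }
    }
  }
  invisible(x)
}
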