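#' Write and read trial datasets as CSV
#'
#' Interchange dialect: one CSV per trial with columns `time_s`,
#' `emg_1..emg_8`, `fx, fy, fz, mx, my, mz`, plus a `manifest.csv` listing
#' `trial_file`, `participant_id`, `class`, `fs` and the clinical scores.
#' Values use RFC-4180-style CSV with a `.` decimal separator.
#'
#' @param dataset A `"trial_dataset"`.
#' @param dir Output directory (created if missing).
#' @param overwrite Refuse to overwrite an existing manifest unless TRUE.
#' @return `write_dataset` returns the manifest path invisibly;
#'   `read_dataset` returns a `"trial_dataset"` (with a NULL config).
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         "; pass overwrite = TRUE to replace it")
  }
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  rows <- list()
  for (tr in dataset$trials) {
    n <- nrow(tr$emg)
    df <- data.frame(time_s = (seq_len(n) - 1L) / tr$fs)
    emg <- tr$emg
    colnames(emg) <- paste0("emg_", seq_len(ncol(emg)))
    df <- cbind(df, emg, tr$loadcell)
    fname <- paste0(tr$trial_id, ".csv")
    utils::write.csv(df, file.path(dir, fname), row.names = FALSE)
    rows[[tr$trial_id]] <- data.frame(
      trial_file = fname, participant_id = tr$participant_id,
      class = tr$class, fs = tr$fs,
      ue_fma = if (is.null(tr$clinical)) NA else tr$clinical$ue_fma,
      reach = if (is.null(tr$clinical)) NA else tr$clinical$reach,
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' @rdname write_dataset
#' @param manifest_path Path to a `manifest.csv` written by
#'   `write_dataset`.
#' @export
read_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  trials <- list()
  for (i in seq_len(nrow(man))) {
    df <- utils::read.csv(file.path(dir, man$trial_file[i]))
    emg <- as.matrix(df[, grep("^emg_", names(df)), drop = FALSE])
    lc <- as.matrix(df[, c("fx", "fy", "fz", "mx", "my", "mz")])
    clin <- if (is.na(man$ue_fma[i])) NULL else
      list(ue_fma = man$ue_fma[i], reach = man$reach[i])
    id <- sub("\\.csv$", "", man$trial_file[i])
    trials[[id]] <- structure(
      list(participant_id = man$participant_id[i], class = man$class[i],
           fs = man$fs[i], emg = emg, loadcell = lc, clinical = clin,
           trial_id = id),
      class = "trial_recording")
  }
  participants <- unique(man[, c("participant_id", "ue_fma", "reach")])
  structure(list(trials = trials, participants = participants,
                 config = NULL),
            class = "trial_dataset")
}

# Small integer fingerprint of a configuration, written into output-table
# headers for provenance.
config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Simulate a cohort and write it to CSV
#'
#' Generates a synthetic dataset from a [generator_config()] and writes
#' the per-trial CSVs, the manifest and the resolved configuration (JSON,
#' for provenance) to `dir`.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @param overwrite Refuse to overwrite an existing manifest unless TRUE.
#' @return The manifest path, invisibly.
#' @export
simulate_dataset_csv <- function(config, dir, overwrite = FALSE) {
  ds <- generate_dataset(config)
  manifest <- write_dataset(ds, dir, overwrite = overwrite)
  cfg <- config
  cfg$geometry <- list(rotation = as.vector(t(cfg$geometry$rotation)),
                       lever_shoulder = cfg$geometry$lever_shoulder,
                       lever_elbow = cfg$geometry$lever_elbow,
                       axis_map = cfg$geometry$axis_map)
  jsonlite::write_json(cfg, file.path(dir, "generator_config.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}

write_table_with_header <- function(df, path, seed, fingerprint) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config=%s", seed, fingerprint), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full offline analysis from a manifest and write report tables
#'
#' End-to-end orchestration: read the trials, evaluate every participant
#' (trial selection, segmentation, feature extraction, trial-wise LOOCV
#' per feature set), and write the report tables to `output_dir`:
#' a cohort-averaged confusion matrix per feature set
#' (`confusion_<set>.csv`), the per-class/average accuracy summary
#' (`summary.csv`), per-participant overall accuracies
#' (`participants.csv`), the normalized AB/AD-vs-ER/IR torque scatter
#' (`scatter.csv`) and the accuracy-vs-clinical-score rank correlations
#' (`correlations.csv`). Every table carries a header comment with the
#' seed and a configuration fingerprint.
#'
#' @param manifest_path Path to a dataset manifest (see
#'   [write_dataset()]).
#' @param output_dir Directory for the report tables (created if
#'   missing).
#' @param feature_sets Feature-set variants to evaluate.
#' @param geometry A [rigid_body_geometry()].
#' @param seed Seed recorded in table headers (the offline analysis itself
#'   is deterministic).
#' @param ... Passed to [evaluate_participant()].
#' @return The `"cohort_result"`, invisibly.
#' @export
run_pipeline <- function(manifest_path, output_dir,
                         feature_sets = c("EMG_TD", "TORQUE", "LOADCELL",
                                          "EMG_LC"),
                         geometry = rigid_body_geometry(), seed = NA, ...) {
  ds <- read_dataset(manifest_path)
  ds$config <- list(geometry = geometry)
  class(ds) <- "trial_dataset"
  res <- evaluate_cohort(ds, feature_sets = feature_sets, ...)
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
    message("created output directory ", output_dir)
  }
  fp <- config_fingerprint(list(manifest_path, feature_sets, seed))
  for (fs in feature_sets) {
    cm <- as.data.frame(round(res$confusions[[fs]], 6))
    cm <- cbind(actual = rownames(cm), cm)
    write_table_with_header(cm, file.path(output_dir,
                                          paste0("confusion_", fs, ".csv")),
                            seed, fp)
  }
  st <- as.data.frame(res$summary$table)
  st <- cbind(class = rownames(st), st)
  write_table_with_header(st, file.path(output_dir, "summary.csv"), seed, fp)
  pt <- do.call(rbind, lapply(res$participants, function(p) {
    data.frame(participant_id = p$participant_id,
               t(vapply(p$loocv, function(l) l$overall_accuracy, 0)))
  }))
  write_table_with_header(pt, file.path(output_dir, "participants.csv"),
                          seed, fp)
  sc <- do.call(rbind, lapply(res$participants, function(p) {
    if (is.null(p$scatter)) return(NULL)
    cbind(participant_id = p$participant_id, p$scatter)
  }))
  if (!is.null(sc)) {
    write_table_with_header(sc, file.path(output_dir, "scatter.csv"),
                            seed, fp)
  }
  if (!is.null(res$correlations)) {
    cr <- do.call(rbind, lapply(names(res$correlations), function(nm) {
      cc <- res$correlations[[nm]]
      data.frame(score = nm, rho = cc$rho, p_value = cc$p_value, n = cc$n)
    }))
    write_table_with_header(cr, file.path(output_dir, "correlations.csv"),
                            seed, fp)
  }
  invisible(res)
}
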