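#' Start indices of overlapped analysis windows
#'
#' Decisions are made from 200 ms windows advanced every 25 ms (175 ms of
#' overlap). Starts are 1-based and spaced by `increment` while a full
#' window fits inside the segment; a segment shorter than one window
#' yields no starts.
#'
#' @param segment_length Segment length in samples.
#' @param window Window length in samples (> 0).
#' @param increment Step between window starts in samples (> 0).
#' @return Integer vector of start indices (possibly empty).
#' @examples
#' window_starts(5000, 200, 25)   # 193 windows
#' @export
window_starts <- function(segment_length, window, increment) {
  if (window <= 0 || increment <= 0) stop("window and increment must be > 0")
  segment_length <- as.integer(segment_length)
  if (segment_length < window) return(integer(0))
  seq.int(1L, segment_length - as.integer(window) + 1L,
          by = as.integer(increment))
}

#' Hudgins time-domain EMG features
#'
#' The four classic window descriptors for myoelectric control:
#' * `mav(x)` — mean absolute value, `mean(|x|)`;
#' * `zero_crossings(x, deadband)` — number of sign changes between
#'   consecutive samples whose amplitude step is at least `deadband`
#'   (zeros count as positive, so zeros alone never create crossings);
#' * `slope_sign_changes(x, deadband)` — number of interior samples where
#'   the first difference changes sign and at least one of the two
#'   adjacent differences has magnitude at least `deadband`;
#' * `waveform_length(x)` — cumulative absolute first difference,
#'   `sum(|diff(x)|)`.
#'
#' @param x Numeric window.
#' @param deadband Non-negative amplitude threshold suppressing
#'   noise-driven counts; 0 disables it.
#' @return A scalar (counts for `zero_crossings` / `slope_sign_changes`).
#' @examples
#' mav(c(1, -3, 2, 0))                        # 1.5
#' zero_crossings(c(1, -1, 1, -1), 0)         # 3
#' slope_sign_changes(c(0, 1, 0, 1, 0), 0)    # 3
#' waveform_length(c(0, 2, -1))               # 5
#' @name hudgins_features
NULL

#' @rdname hudgins_features
#' @export
mav <- function(x) {
  if (length(x) == 0L) stop("empty window")
  mean(abs(x))
}

#' @rdname hudgins_features
#' @export
zero_crossings <- function(x, deadband = 0) {
  if (length(x) == 0L) stop("empty window")
  if (deadband < 0) stop("deadband must be >= 0")
  if (length(x) == 1L) return(0L)
  s <- x >= 0
  n <- length(x)
  sum(s[-1L] != s[-n] & abs(diff(x)) >= deadband)
}

#' @rdname hudgins_features
#' @export
slope_sign_changes <- function(x, deadband = 0) {
  if (length(x) < 3L) stop("window must have at least 3 samples")
  if (deadband < 0) stop("deadband must be >= 0")
  d <- diff(x)
  s <- d >= 0
  m <- length(d)
  sum(s[-1L] != s[-m] & pmax(abs(d[-1L]), abs(d[-m])) >= deadband)
}

#' @rdname hudgins_features
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) stop("window must have at least 2 samples")
  sum(abs(diff(x)))
}

#' Dimensionality of each feature-set variant
#'
#' @param feature_set One of `"EMG_TD"`, `"LOADCELL"`, `"TORQUE"`,
#'   `"EMG_LC"`.
#' @return 32, 6, 4 or 38: four time-domain features per EMG channel,
#'   per-channel window means for the 6 load-cell or 4 torque channels,
#'   or EMG features concatenated with load-cell means.
#' @export
feature_set_dim <- function(feature_set) {
  switch(match.arg(feature_set, c("EMG_TD", "LOADCELL", "TORQUE", "EMG_LC")),
         EMG_TD = 32L, LOADCELL = 6L, TORQUE = 4L, EMG_LC = 38L)
}

# Windowed Hudgins features for one channel, vectorized over windows.
# idx: window x n_windows index matrix into x.
hudgins_windowed <- function(x, idx, deadband) {
  X <- matrix(x[idx], nrow(idx), ncol(idx))
  w <- nrow(X)
  D <- X[-1L, , drop = FALSE] - X[-w, , drop = FALSE]
  S <- X >= 0
  zc <- colSums((S[-1L, , drop = FALSE] != S[-w, , drop = FALSE]) &
                  abs(D) >= deadband)
  SD <- D >= 0
  m <- nrow(D)
  ssc <- colSums((SD[-1L, , drop = FALSE] != SD[-m, , drop = FALSE]) &
                   (pmax(abs(D[-1L, , drop = FALSE]),
                         abs(D[-m, , drop = FALSE])) >= deadband))
  cbind(mav = colMeans(abs(X)), zc = zc, ssc = ssc,
        wl = colSums(abs(D)))
}

#' Extract a feature matrix from one trial
#'
#' Builds overlapped windows inside each contiguous active run (windows
#' never span the gap between runs; a trailing partial window is dropped)
#' and computes one of the four feature-set variants per window:
#' `"EMG_TD"` (4 Hudgins features x 8 channels, channel-major: ch1 mav,
#' zc, ssc, wl, then ch2, ...), `"LOADCELL"` (mean of each of the 6 raw
#' load-cell channels), `"TORQUE"` (mean of each of the 4 joint torques)
#' or `"EMG_LC"` (EMG_TD followed by LOADCELL).
#'
#' @param emg n x 8 matrix of (filtered) EMG.
#' @param loadcell n x 6 matrix of raw load-cell channels.
#' @param torque n x 4 matrix of joint torques.
#' @param segments Data frame from [segment_active()] (`start`, `end`).
#' @param feature_set One of `"EMG_TD"`, `"LOADCELL"`, `"TORQUE"`,
#'   `"EMG_LC"`.
#' @param fs Sampling rate (Hz).
#' @param window_ms,increment_ms Window length and decision increment in
#'   milliseconds.
#' @param deadband Amplitude deadband for the zero-crossing and
#'   slope-sign-change counts.
#' @param label,trial_id Class label and trial identifier attached to
#'   every window row.
#' @return An object of class `"feature_matrix"`: list with `values`
#'   (windows x D), `labels`, `trial_ids`, `feature_set` and
#'   `feature_names`. Zero windows is a valid result (0-row matrix).
#' @export
extract_features <- function(emg, loadcell, torque, segments, feature_set,
                             fs, window_ms = 200, increment_ms = 25,
                             deadband = 0, label = NA_character_,
                             trial_id = NA_character_) {
  feature_set <- match.arg(feature_set,
                           c("EMG_TD", "LOADCELL", "TORQUE", "EMG_LC"))
  w <- as.integer(round(window_ms / 1000 * fs))
  inc <- as.integer(round(increment_ms / 1000 * fs))
  starts <- integer(0)
  for (i in seq_len(nrow(segments))) {
    len <- segments$end[i] - segments$start[i] + 1L
    starts <- c(starts, segments$start[i] - 1L + window_starts(len, w, inc))
  }
  D <- feature_set_dim(feature_set)
  fnames <- feature_names(feature_set, colnames(emg), colnames(loadcell))
  if (length(starts) == 0L) {
    vals <- matrix(numeric(0), 0L, D, dimnames = list(NULL, fnames))
    return(structure(list(values = vals, labels = character(0),
                          trial_ids = character(0), feature_set = feature_set,
                          feature_names = fnames),
                     class = "feature_matrix"))
  }
  idx <- outer(0:(w - 1L), starts, "+")
  win_means <- function(m) {
    out <- sapply(seq_len(ncol(m)), function(j) {
      colMeans(matrix(m[, j][idx], w, length(starts)))
    })
    matrix(out, length(starts), ncol(m))
  }
  emg_td <- function() {
    do.call(cbind, lapply(seq_len(ncol(emg)), function(ch) {
      hudgins_windowed(emg[, ch], idx, deadband)
    }))
  }
  vals <- switch(feature_set,
                 EMG_TD = emg_td(),
                 LOADCELL = win_means(loadcell),
                 TORQUE = win_means(torque),
                 EMG_LC = cbind(emg_td(), win_means(loadcell)))
  if (!all(is.finite(vals))) stop("non-finite feature values")
  dimnames(vals) <- list(NULL, fnames)
  structure(list(values = vals,
                 labels = rep(label, length(starts)),
                 trial_ids = rep(trial_id, length(starts)),
                 feature_set = feature_set,
                 feature_names = fnames),
            class = "feature_matrix")
}

feature_names <- function(feature_set, emg_names = NULL, lc_names = NULL) {
  if (is.null(emg_names)) emg_names <- paste0("emg", 1:8)
  if (is.null(lc_names)) lc_names <- c("fx", "fy", "fz", "mx", "my", "mz")
  td <- as.vector(t(outer(emg_names, c("mav", "zc", "ssc", "wl"),
                          paste, sep = "_")))
  switch(feature_set,
         EMG_TD = td,
         LOADCELL = paste0(lc_names, "_mean"),
         TORQUE = paste0(torque_dof_names(), "_mean"),
         EMG_LC = c(td, paste0(lc_names, "_mean")))
}

# Stack per-trial feature matrices (same feature set) into one.
rbind_features <- function(fm_list) {
  fs <- unique(vapply(fm_list, function(f) f$feature_set, ""))
  stopifnot(length(fs) == 1L)
  structure(list(values = do.call(rbind, lapply(fm_list, `[[`, "values")),
                 labels = unlist(lapply(fm_list, `[[`, "labels"),
                                 use.names = FALSE),
                 trial_ids = unlist(lapply(fm_list, `[[`, "trial_ids"),
                                    use.names = FALSE),
                 feature_set = fs,
                 feature_names = fm_list[[1L]]$feature_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix (", x$feature_set, "): ", nrow(x$values),
      " windows x ", ncol(x$values), " features\n", sep = "")
  invisible(x)
}
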