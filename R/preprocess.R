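#' Notch filter power-line interference and its harmonics
#'
#' Removes mains interference from an offline recording with a cascade of
#' Butterworth band-stop filters at the fundamental and its harmonics
#' (by default 58-62 Hz, 118-122 Hz, ... while the upper notch edge stays
#' below both `max_harmonic` and Nyquist). Each stop band is applied
#' forward-backward for zero phase, with odd-reflection padding at both
#' ends to suppress edge transients; the output has the same length as the
#' input.
#'
#' @param x Numeric vector, one channel.
#' @param fs Sampling rate in Hz.
#' @param fundamental Power-line frequency in Hz.
#' @param half_width Half width of each stop band in Hz.
#' @param order Overall Butterworth order of each band-stop section (must
#'   be even; a band-stop of order 6 comes from a 3rd-order prototype).
#' @param max_harmonic Do not place notches whose upper edge reaches this
#'   frequency (Hz); defaults to the 450 Hz edge of the usual surface-EMG
#'   hardware band.
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' x <- sin(2 * pi * 35 * t) + 0.5 * sin(2 * pi * 60 * t)
#' y <- notch_filter(x, fs = 1000)
#' @export
notch_filter <- function(x, fs, fundamental = 60, half_width = 2,
                         order = 6, max_harmonic = 450) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (order < 2 || order %% 2 != 0) stop("order must be a positive even number")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L * (order + 1L)) {
    stop("signal too short for stable filtering (need >= ", 3L * (order + 1L),
         " samples)")
  }
  f_top <- min(max_harmonic, fs / 2)
  if (fs <= 2 * fundamental + 2 * half_width) {
    stop("fs too low: fundamental notch would reach Nyquist")
  }
  ks <- seq_len(floor((f_top - half_width) / fundamental))
  ks <- ks[ks * fundamental + half_width < f_top]
  # odd-reflection padding; transients of the narrow notches decay over
  # O(fs / half_width) samples, so pad about 2 s worth when available
  npad <- min(n - 1L, as.integer(round(2 * fs)))
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- c(pre, x, post)
  for (k in ks) {
    w <- c(k * fundamental - half_width, k * fundamental + half_width) / (fs / 2)
    bf <- signal::butter(order %/% 2L, w, type = "stop")
    y <- signal::filtfilt(bf, y)
  }
  y[(npad + 1L):(npad + n)]
}

#' Maximum voluntary torque via a trailing moving average
#'
#' The maximum voluntary torque (MVT) of a trial is the largest value of
#' the trailing moving average (default 200 ms) of the torque in the
#' tested direction. Pass the primary-axis torque already rectified toward
#' the tested direction (see [primary_torque()]).
#'
#' @param x Numeric vector: sign-rectified primary-direction torque (N m).
#' @param fs Sampling rate in Hz.
#' @param window_ms Moving-average window in milliseconds.
#' @return List with `mvt` (N m) and `index` (sample index of the end of
#'   the best window).
#' @examples
#' max_voluntary_torque(c(rep(0, 300), rep(5, 400), rep(0, 300)), fs = 1000)
#' @export
max_voluntary_torque <- function(x, fs, window_ms = 200) {
  x <- as.numeric(x)
  w <- max(1L, as.integer(round(window_ms / 1000 * fs)))
  if (length(x) < w) {
    stop("series shorter than one moving-average window (", w, " samples)")
  }
  ma <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
  idx <- which.max(ma)            # NAs at the head never win which.max
  list(mvt = ma[idx], index = idx)
}

#' Primary-direction torque of a trial, rectified toward the tested class
#'
#' @param torques A `"joint_torque_series"` (see [compute_joint_torques()]).
#' @param class Task-class code (one of [class_order()]).
#' @return Numeric vector: `primary_sign * torque[, primary_axis]`, so that
#'   effort in the instructed direction is positive.
#' @export
primary_torque <- function(torques, class) {
  info <- class_info(class)
  info$primary_sign * torques$torque[, info$primary_axis]
}

#' Retain the three largest-MVT trials of one direction
#'
#' The protocol records 3-6 trials per direction, aiming for three trial
#' maxima within 10% of each other with the last trial not the greatest
#' (otherwise effort may still be increasing). Analysis always uses the
#' three trials with the largest MVT; the stop criterion is reported as a
#' flag, not enforced.
#'
#' @param mvts Numeric vector of per-trial MVTs in acquisition order
#'   (length >= 3).
#' @return List with `selected` (indices of the 3 retained trials, in
#'   acquisition order; ties broken toward earlier trials) and
#'   `criterion_met` (logical: top-3 spread `(max - min) / max <= 0.10`
#'   and the chronologically last trial is not strictly greater than every
#'   other trial).
#' @examples
#' select_trials(c(10, 9.6, 9.8))
#' select_trials(c(8, 9, 12))
#' @export
select_trials <- function(mvts) {
  mvts <- as.numeric(mvts)
  n <- length(mvts)
  if (n < 3L) stop("need at least 3 trials per direction")
  if (!all(is.finite(mvts))) stop("MVTs must be finite")
  ord <- order(-mvts, seq_len(n))
  selected <- sort(ord[1:3])
  top <- mvts[selected]
  spread_ok <- (max(top) - min(top)) / max(top) <= 0.10
  last_greatest <- mvts[n] > max(mvts[-n])
  list(selected = selected, criterion_met = spread_ok && !last_greatest)
}

#' Segment the active portion of a trial
#'
#' Returns the maximal contiguous runs of samples where the sign-rectified
#' primary-axis torque exceeds `threshold * mvt` (strictly). Runs shorter
#' than one analysis window are kept in the list; they simply contribute
#' no windows downstream. An empty result (no sample above threshold) is
#' valid.
#'
#' @param primary Numeric vector: sign-rectified primary-direction torque.
#' @param mvt Maximum voluntary torque for this direction (> 0).
#' @param threshold Fraction of MVT defining "active" (default 0.20).
#' @return Data frame with columns `start` and `end`: 1-based inclusive
#'   sample ranges, disjoint and sorted.
#' @examples
#' segment_active(c(0, 1, 5, 6, 5, 1, 0), mvt = 6)
#' @export
segment_active <- function(primary, mvt, threshold = 0.20) {
  if (!is.numeric(mvt) || length(mvt) != 1L || !is.finite(mvt) || mvt <= 0) {
    stop("mvt must be a positive scalar")
  }
  above <- as.numeric(primary) > threshold * mvt
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
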