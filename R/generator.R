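#' Default class-by-DOF plateau torque directions (N m)
#'
#' One row per task class (order of [class_order()]), one column per torque
#' DOF (order of [torque_dof_names()]). Entries are the signed mean torque
#' at the effort plateau. Each row is dominated by its primary axis;
#' secondary entries are small same-synergy torques, as typically seen in
#' maximal single-DOF isometric efforts of moderately impaired arms.
#'
#' @return 8 x 4 numeric matrix with dimnames.
#' @export
default_torque_directions <- function() {
  m <- rbind(
    EF  = c(  2,   1,   1,  25),
    AB  = c( 30,   4,   3,   5),
    ER  = c(  4,   2,  14,   3),
    HAB = c(  3,  22,   2,   2),
    EE  = c( -2,  -1,  -1, -22),
    AD  = c(-32,  -5,  -3,  -4),
    IR  = c( -5,  -2, -16,  -3),
    HAD = c( -3, -24,  -2,  -2)
  )
  colnames(m) <- torque_dof_names()
  m
}

#' Default class-by-muscle EMG activation gains
#'
#' One row per task class, one column per recorded muscle (anterior,
#' intermediate and posterior deltoid, pectoralis major, biceps, triceps
#' long and lateral heads, brachioradialis). A gain g scales the standard
#' deviation of the band-limited EMG surrogate at the effort plateau
#' (signal units, here mV). The rows overlap deliberately: with surface
#' electrodes on major muscles only, adduction and internal rotation are
#' both pectoralis-dominant and abduction and external rotation share
#' deltoid activity, so EMG alone separates classes less sharply than the
#' load cell does.
#'
#' @return 8 x 8 non-negative numeric matrix with dimnames.
#' @export
default_activation <- function() {
  m <- rbind(
    EF  = c(0.08, 0.05, 0.03, 0.05, 0.45, 0.03, 0.03, 0.35),
    AB  = c(0.30, 0.45, 0.15, 0.08, 0.12, 0.05, 0.05, 0.05),
    ER  = c(0.10, 0.25, 0.35, 0.03, 0.10, 0.08, 0.05, 0.05),
    HAB = c(0.05, 0.30, 0.45, 0.03, 0.05, 0.10, 0.08, 0.03),
    EE  = c(0.03, 0.05, 0.10, 0.05, 0.03, 0.40, 0.38, 0.05),
    AD  = c(0.15, 0.05, 0.05, 0.42, 0.08, 0.20, 0.10, 0.05),
    IR  = c(0.28, 0.05, 0.03, 0.40, 0.10, 0.10, 0.08, 0.05),
    HAD = c(0.35, 0.08, 0.03, 0.45, 0.12, 0.05, 0.05, 0.05)
  )
  colnames(m) <- c("ant_deltoid", "mid_deltoid", "post_deltoid", "pect_major",
                   "biceps", "tri_long", "tri_lat", "brachiorad")
  m
}

#' Benchmark activation matrices
#'
#' Two idealized alternatives to [default_activation()] for studying how
#' classifier performance depends on EMG separability:
#' `separable_activation()` gives every class one dominant muscle
#' (gain 0.5) with a uniform 0.03 background, an idealized best case in
#' which EMG alone carries full class information;
#' `overlapping_activation()` gives all classes a nearly identical
#' moderate activation pattern (0.20 everywhere, with only a 0.02 bump on
#' one class-specific muscle), so EMG is almost uninformative while the
#' torque channels remain fully separable. The muscle assignments are
#' schematic, not physiological.
#'
#' @return 8 x 8 non-negative numeric matrix with dimnames.
#' @export
separable_activation <- function() {
  m <- matrix(0.03, 8L, 8L,
              dimnames = dimnames(default_activation()))
  dominant <- c(EF = "biceps", AB = "mid_deltoid", ER = "post_deltoid",
                HAB = "ant_deltoid", EE = "tri_long", AD = "pect_major",
                IR = "tri_lat", HAD = "brachiorad")
  for (cl in names(dominant)) m[cl, dominant[cl]] <- 0.5
  m
}

#' @rdname separable_activation
#' @export
overlapping_activation <- function() {
  m <- matrix(0.20, 8L, 8L,
              dimnames = dimnames(default_activation()))
  for (i in seq_len(8L)) m[i, i] <- 0.22
  m
}

#' Configuration of the synthetic-trial generator
#'
#' Bundles everything needed to simulate a cohort of isometric-strength
#' sessions: per-class torque directions and muscle activations, trial
#' timing, noise levels, power-line interference, the rigid-body geometry
#' used to turn latent joint torques into load-cell channels, and the
#' abnormal-synergy coupling knob.
#'
#' `synergy_coupling` in \[0, 1\] mixes the AB and ER class profiles (and AD
#' with IR) in both the torque-direction and activation matrices: 0 leaves
#' the classes unmixed, 1 makes the paired rows identical. This emulates
#' participants who produce abduction and external rotation (adduction and
#' internal rotation) with the same coupled strategy, the dominant source
#' of misclassification in this task.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_class Trials recorded per direction (3-6).
#' @param fs Sampling rate (Hz).
#' @param trial_duration Trial length (s).
#' @param torque_direction_matrix 8 x 4 signed plateau torques (N m); each
#'   row must be dominated (in absolute value) by its class's primary axis.
#' @param activation_matrix 8 x 8 non-negative EMG gains.
#' @param emg_noise_floor Resting EMG standard deviation (signal units).
#' @param powerline_amplitude Amplitude of additive mains interference
#'   (signal units).
#' @param powerline_freq Mains frequency (Hz).
#' @param synergy_coupling Coupling strength in \[0, 1\]; the default 0.5
#'   represents a moderately impaired cohort.
#' @param envelope_ramp,envelope_hold Ramp and hold durations (s) of the
#'   trapezoidal effort envelope; `2 * ramp + hold <= trial_duration`.
#' @param torque_noise_sd Additive Gaussian noise on each torque DOF (N m).
#' @param plateau_jitter Per-trial multiplicative jitter of the plateau
#'   amplitude, uniform in `1 +- plateau_jitter`, so trial maxima vary and
#'   the 10% trial-selection rule is exercised.
#' @param geometry A [rigid_body_geometry()].
#' @param seed Integer seed for [generate_dataset()].
#' @return An object of class `"generator_config"` (a validated list).
#' @export
generator_config <- function(n_participants = 2,
                             trials_per_class = 3,
                             fs = 1000,
                             trial_duration = 5,
                             torque_direction_matrix = default_torque_directions(),
                             activation_matrix = default_activation(),
                             emg_noise_floor = 0.01,
                             powerline_amplitude = 0.02,
                             powerline_freq = 60,
                             synergy_coupling = 0.5,
                             envelope_ramp = 1,
                             envelope_hold = 2,
                             torque_noise_sd = 0.5,
                             plateau_jitter = 0.05,
                             geometry = rigid_body_geometry(),
                             seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              trials_per_class = as.integer(trials_per_class),
              fs = fs, trial_duration = trial_duration,
              torque_direction_matrix = as.matrix(torque_direction_matrix),
              activation_matrix = as.matrix(activation_matrix),
              emg_noise_floor = emg_noise_floor,
              powerline_amplitude = powerline_amplitude,
              powerline_freq = powerline_freq,
              synergy_coupling = synergy_coupling,
              envelope_ramp = envelope_ramp,
              envelope_hold = envelope_hold,
              torque_noise_sd = torque_noise_sd,
              plateau_jitter = plateau_jitter,
              geometry = geometry,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1")
  if (cfg$trials_per_class < 3L || cfg$trials_per_class > 6L) {
    stop("trials_per_class must be in [3, 6]")
  }
  if (cfg$fs <= 0 || cfg$trial_duration <= 0) {
    stop("fs and trial_duration must be positive")
  }
  tdm <- cfg$torque_direction_matrix
  tc <- task_classes()
  if (!identical(dim(tdm), c(8L, 4L)) ||
      !identical(rownames(tdm), tc$code)) {
    stop("torque_direction_matrix must be 8 x 4 with rows named ",
         paste(tc$code, collapse = ", "))
  }
  for (i in seq_len(8L)) {
    if (which.max(abs(tdm[i, ])) != tc$primary_axis[i]) {
      stop("torque_direction_matrix row ", tc$code[i],
           " is not dominated by its primary axis")
    }
    if (sign(tdm[i, tc$primary_axis[i]]) != tc$primary_sign[i]) {
      stop("torque_direction_matrix row ", tc$code[i],
           " has the wrong primary sign")
    }
  }
  am <- cfg$activation_matrix
  if (!identical(dim(am), c(8L, 8L)) || !identical(rownames(am), tc$code)) {
    stop("activation_matrix must be 8 x 8 with class row names")
  }
  if (any(am < 0)) stop("activation gains must be >= 0")
  if (cfg$synergy_coupling < 0 || cfg$synergy_coupling > 1) {
    stop("synergy_coupling must be in [0, 1]")
  }
  if (cfg$envelope_ramp < 0 || cfg$envelope_hold < 0 ||
      2 * cfg$envelope_ramp + cfg$envelope_hold > cfg$trial_duration) {
    stop("need ramp >= 0, hold >= 0 and 2*ramp + hold <= trial_duration")
  }
  if (cfg$torque_noise_sd < 0 || cfg$emg_noise_floor < 0 ||
      cfg$powerline_amplitude < 0) {
    stop("noise levels must be >= 0")
  }
  invisible(cfg)
}

#' Trapezoidal effort envelope
#'
#' Unit-amplitude ramp-hold-release profile: zero, linear ramp up over
#' `ramp` seconds, plateau at exactly 1 for `hold` seconds, linear ramp
#' down, zero again. The active portion is centred in the trial.
#'
#' @param duration Trial length (s), > 0.
#' @param fs Sampling rate (Hz), > 0.
#' @param ramp,hold Ramp and hold durations (s); `2 * ramp + hold` must not
#'   exceed `duration`.
#' @return Numeric vector of `round(duration * fs)` values in \[0, 1\].
#' @examples
#' env <- torque_envelope(5, 1000, ramp = 1, hold = 2)
#' range(env)
#' @export
torque_envelope <- function(duration, fs, ramp = 1, hold = 2) {
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (ramp < 0 || hold < 0) stop("ramp and hold must be >= 0")
  if (2 * ramp + hold > duration) {
    stop("2*ramp + hold exceeds the trial duration")
  }
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  t0 <- (duration - (2 * ramp + hold)) / 2
  env <- numeric(n)
  if (ramp > 0) {
    up <- t >= t0 & t < t0 + ramp
    env[up] <- (t[up] - t0) / ramp
    down <- t > t0 + ramp + hold & t < t0 + 2 * ramp + hold
    env[down] <- (t0 + 2 * ramp + hold - t[down]) / ramp
  }
  env[t >= t0 + ramp & t <= t0 + ramp + hold] <- 1
  if (ramp == 0 && hold > 0) env[t >= t0 & t <= t0 + hold] <- 1
  env
}

#' Mix class profiles to emulate abnormal synergy
#'
#' Replaces the AB and ER rows (and, symmetrically, AD and IR) of the
#' torque-direction and activation matrices by the convex mixtures
#' `(1 - c/2) * own + (c/2) * partner`. At `c = 0` the matrices are
#' returned unchanged; at `c = 1` each paired row equals the pair mean, so
#' the two classes become indistinguishable in their mean profiles.
#'
#' @param config A [generator_config()] (its `synergy_coupling` is used
#'   unless `coupling` is given).
#' @param coupling Optional override of the coupling strength in \[0, 1\].
#' @return List with elements `torque_direction_matrix` and
#'   `activation_matrix`; the input config is not modified.
#' @examples
#' cfg <- generator_config(synergy_coupling = 1)
#' mixed <- apply_synergy_coupling(cfg)
#' all.equal(mixed$torque_direction_matrix["AB", ],
#'           mixed$torque_direction_matrix["ER", ])
#' @export
apply_synergy_coupling <- function(config, coupling = config$synergy_coupling) {
  if (!is.numeric(coupling) || length(coupling) != 1L ||
      coupling < 0 || coupling > 1) {
    stop("coupling must be a scalar in [0, 1]")
  }
  mix_pair <- function(m, a, b) {
    ra <- m[a, ]; rb <- m[b, ]
    m[a, ] <- (1 - coupling / 2) * ra + (coupling / 2) * rb
    m[b, ] <- (1 - coupling / 2) * rb + (coupling / 2) * ra
    m
  }
  tdm <- mix_pair(mix_pair(config$torque_direction_matrix, "AB", "ER"),
                  "AD", "IR")
  am <- mix_pair(mix_pair(config$activation_matrix, "AB", "ER"), "AD", "IR")
  list(torque_direction_matrix = tdm, activation_matrix = am)
}

# Band-limited (20-450 Hz) unit-variance Gaussian noise, the standard
# interference-pattern surrogate for surface EMG.
bandlimited_noise <- function(n, fs, low = 20, high = 450) {
  high <- min(high, 0.99 * fs / 2)
  bp <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  z <- signal::filtfilt(bp, stats::rnorm(n))
  z / stats::sd(z)
}

#' Simulate one labeled trial
#'
#' Forward model of a single 5 s maximal isometric effort: a latent 4-DOF
#' joint-torque series (trapezoidal envelope times the class's coupled
#' torque-direction row, plus Gaussian noise) is pushed backwards through
#' the rigid-body transform to produce the 6 load-cell channels, so that
#' [compute_joint_torques()] recovers the latent torques up to the added
#' noise. Each EMG channel is band-limited (20-450 Hz) Gaussian noise whose
#' standard deviation follows `emg_noise_floor + gain * envelope`, plus a
#' mains sinusoid of amplitude `powerline_amplitude`. Uses the current R
#' RNG state; seed externally (or via [generate_dataset()]) for
#' reproducibility.
#'
#' @param config A [generator_config()].
#' @param class Task-class code.
#' @param participant_id Identifier stored on the trial.
#' @param plateau_scale Multiplier on the plateau torque (per-trial jitter).
#' @return An object of class `"trial_recording"`: list with
#'   `participant_id`, `class`, `fs`, `emg` (n x 8), `loadcell` (n x 6) and
#'   `clinical` (possibly NULL).
#' @export
generate_trial <- function(config, class, participant_id = "P1",
                           plateau_scale = 1) {
  validate_generator_config(config)
  stopifnot(class %in% class_order())
  mixed <- apply_synergy_coupling(config)
  n <- as.integer(round(config$trial_duration * config$fs))
  env <- torque_envelope(config$trial_duration, config$fs,
                         config$envelope_ramp, config$envelope_hold)
  dir_row <- mixed$torque_direction_matrix[class, ] * plateau_scale
  tau <- outer(env, dir_row)
  if (config$torque_noise_sd > 0) {
    tau <- tau + matrix(stats::rnorm(n * 4L, sd = config$torque_noise_sd),
                        n, 4L)
  }
  loadcell <- invert_joint_torques(tau, config$geometry)
  gains <- mixed$activation_matrix[class, ] * plateau_scale
  t <- (seq_len(n) - 1L) / config$fs
  mains <- config$powerline_amplitude *
    sin(2 * pi * config$powerline_freq * t)
  emg <- matrix(0, n, 8L, dimnames = list(NULL, colnames(gains)))
  for (ch in seq_len(8L)) {
    amp <- config$emg_noise_floor + gains[ch] * env
    emg[, ch] <- bandlimited_noise(n, config$fs) * amp + mains
  }
  colnames(emg) <- colnames(config$activation_matrix)
  structure(list(participant_id = participant_id, class = class,
                 fs = config$fs, emg = emg, loadcell = loadcell,
                 clinical = NULL),
            class = "trial_recording")
}

#' Simulate a full cohort
#'
#' Generates `n_participants x 8 classes x trials_per_class` labeled
#' trials. Each participant receives clinical scores (upper-extremity
#' Fugl-Meyer, uniform integer 10-45, the moderate-to-severe inclusion
#' range; reach fraction, uniform in \[0, 1\]); the scores carry no built-in
#' relationship with signal quality. Per-trial plateau amplitudes are
#' jittered by `plateau_jitter`. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An object of class `"trial_dataset"`: list with `trials` (list
#'   of [generate_trial()] outputs, each tagged with a `trial_id`),
#'   `participants` (data frame of ids and clinical scores) and `config`.
#' @examples
#' ds <- generate_dataset(generator_config(n_participants = 1, seed = 7))
#' length(ds$trials)
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  classes <- class_order()
  trials <- list()
  participants <- data.frame(participant_id = character(0),
                             ue_fma = integer(0), reach = numeric(0))
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    clin <- list(ue_fma = sample(10:45, 1L), reach = stats::runif(1))
    participants <- rbind(participants,
                          data.frame(participant_id = pid,
                                     ue_fma = clin$ue_fma,
                                     reach = clin$reach))
    for (cl in classes) {
      for (k in seq_len(config$trials_per_class)) {
        scale <- 1 + stats::runif(1, -config$plateau_jitter,
                                  config$plateau_jitter)
        tr <- generate_trial(config, cl, pid, plateau_scale = scale)
        tr$clinical <- clin
        tr$trial_id <- sprintf("%s_%s_%d", pid, cl, k)
        trials[[tr$trial_id]] <- tr
      }
    }
  }
  structure(list(trials = trials, participants = participants,
                 config = config),
            class = "trial_dataset")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("Trial", if (!is.null(x$trial_id)) x$trial_id else "",
      "- class", x$class, "participant", x$participant_id, "\n")
  cat(nrow(x$emg), "samples at", x$fs, "Hz; 8 EMG + 6 load-cell channels\n")
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Synthetic trial dataset:", length(x$trials), "trials,",
      nrow(x$participants), "participants,",
      x$config$trials_per_class, "trials/class, coupling",
      x$config$synergy_coupling, "\n")
  invisible(x)
}
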