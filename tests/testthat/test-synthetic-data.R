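test_that("task class table satisfies the protocol structure", {
  tc <- task_classes()
  expect_equal(nrow(tc), 8)
  expect_setequal(tc$code[tc$synergy_group == "flexion"],
                  c("EF", "AB", "ER", "HAB"))
  expect_setequal(tc$code[tc$synergy_group == "extension"],
                  c("EE", "AD", "IR", "HAD"))
  # each torque axis has exactly two classes with opposite signs
  for (ax in 1:4) {
    signs <- tc$primary_sign[tc$primary_axis == ax]
    expect_equal(sort(signs), c(-1, 1))
  }
})

test_that("torque envelope has the stated trapezoidal shape", {
  env <- torque_envelope(5, 1000, ramp = 1, hold = 2)
  expect_length(env, 5000)
  expect_true(all(env >= 0 & env <= 1))
  t <- (seq_along(env) - 1) / 1000
  plateau <- t >= 1.5 & t <= 3.5        # central 2 s
  expect_true(all(env[plateau] == 1))
  expect_identical(env[1], 0)
  expect_identical(env[5000], 0)
  # degenerate: no ramp, hold over the full trial
  expect_true(all(torque_envelope(5, 1000, ramp = 0, hold = 5) == 1))
  # trapezoid area oracle: discrete sum ~ (ramp + hold) * fs
  env2 <- torque_envelope(5, 1000, ramp = 1.5, hold = 1)
  expect_equal(sum(env2), (1.5 + 1) * 1000, tolerance = 1e-3)
  expect_error(torque_envelope(-1, 1000), "positive")
  expect_error(torque_envelope(5, 1000, ramp = 2, hold = 2), "exceeds")
})

test_that("synergy coupling mixes exactly the AB/ER and AD/IR rows", {
  cfg <- generator_config(torque_direction_matrix = unit_directions(),
                          synergy_coupling = 0)
  expect_identical(apply_synergy_coupling(cfg)$torque_direction_matrix,
                   cfg$torque_direction_matrix)
  mixed <- apply_synergy_coupling(cfg, coupling = 0.5)
  expect_equal(unname(mixed$torque_direction_matrix["AB", ]),
               c(3, 0, 0.75, 0))   # (1 - c/2) * (4,0,0,0) + (c/2) * (0,0,3,0)
  # untouched rows unchanged
  expect_identical(mixed$torque_direction_matrix["EF", ],
                   cfg$torque_direction_matrix["EF", ])
  full <- apply_synergy_coupling(cfg, coupling = 1)
  pair_mean <- (cfg$torque_direction_matrix["AB", ] +
                  cfg$torque_direction_matrix["ER", ]) / 2
  expect_equal(full$torque_direction_matrix["AB", ], pair_mean)
  expect_equal(full$torque_direction_matrix["ER", ], pair_mean)
  expect_error(apply_synergy_coupling(cfg, coupling = 1.2), "\\[0, 1\\]")
})

test_that("coupling monotonically closes the AB-ER direction angle", {
  cfg <- generator_config()
  ang <- vapply(c(0, 0.5, 1), function(cc) {
    m <- apply_synergy_coupling(cfg, coupling = cc)$torque_direction_matrix
    a <- m["AB", ]; b <- m["ER", ]
    acos(min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))
  }, 0)
  expect_true(all(diff(ang) <= 1e-12))
  expect_lt(ang[3], 1e-6)
})

test_that("generated trials obey the zero, round-trip and determinism contracts", {
  zero_cfg <- generator_config(
    activation_matrix = matrix(0, 8, 8,
                               dimnames = dimnames(default_activation())),
    emg_noise_floor = 0, powerline_amplitude = 0)
  tr <- generate_trial(zero_cfg, "AB")
  expect_true(all(tr$emg == 0))

  clean <- generator_config(torque_direction_matrix = unit_directions(),
                            torque_noise_sd = 0, synergy_coupling = 0)
  tr2 <- generate_trial(clean, "EF")
  jt <- compute_joint_torques(tr2$loadcell, clean$geometry, fs = clean$fs)
  env <- torque_envelope(5, 1000, clean$envelope_ramp, clean$envelope_hold)
  expect_equal(jt$torque[, "efee"], 5 * env, tolerance = 1e-9)
  expect_true(max(abs(jt$torque[, c("abad", "habhad", "erir")])) < 1e-9)

  cfg <- quick_config()
  set.seed(5); a <- generate_trial(cfg, "IR")
  set.seed(5); b <- generate_trial(cfg, "IR")
  expect_identical(a, b)
})

test_that("latent torques survive the full forward/inverse transform with noise", {
  # round-trip property at torque_noise_sd = 0: relative error < 1e-9
  cfg <- generator_config(torque_noise_sd = 0, synergy_coupling = 0.3)
  set.seed(9)
  for (cl in c("AB", "EE", "HAD")) {
    tr <- generate_trial(cfg, cl)
    jt <- compute_joint_torques(tr$loadcell, cfg$geometry, fs = cfg$fs)
    mixed <- apply_synergy_coupling(cfg)
    env <- torque_envelope(cfg$trial_duration, cfg$fs, cfg$envelope_ramp,
                           cfg$envelope_hold)
    latent <- outer(env, mixed$torque_direction_matrix[cl, ])
    expect_lt(max(abs(jt$torque - latent)) / max(abs(latent)), 1e-9)
  }
})

test_that("dataset generation yields the full factorial of labeled trials", {
  cfg <- generator_config(n_participants = 2, trials_per_class = 3,
                          trial_duration = 1, envelope_ramp = 0.25,
                          envelope_hold = 0.5, seed = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds$trials, 2 * 8 * 3)
  labs <- vapply(ds$trials, `[[`, "", "class")
  pids <- vapply(ds$trials, `[[`, "", "participant_id")
  expect_true(all(table(pids, labs) == 3))
  # trial ids encode (participant, class) consistently
  expect_true(all(mapply(function(id, p, cl) startsWith(id, paste(p, cl, sep = "_")),
                         names(ds$trials), pids, labs)))
  # clinical scores attached and within range
  expect_true(all(ds$participants$ue_fma >= 10 & ds$participants$ue_fma <= 45))
  expect_true(all(ds$participants$reach >= 0 & ds$participants$reach <= 1))
  # six trials per class doubles the count
  cfg6 <- generator_config(n_participants = 2, trials_per_class = 6,
                           trial_duration = 1, envelope_ramp = 0.25,
                           envelope_hold = 0.5, seed = 3)
  expect_length(generate_dataset(cfg6)$trials, 96)
  # determinism of the whole dataset
  expect_identical(generate_dataset(cfg), ds)
})

test_that("EMG spectrum shows a 60 Hz line only when mains interference is on", {
  peak_at_60 <- function(powerline) {
    cfg <- quick_config(powerline_amplitude = powerline, seed = 77)
    set.seed(13)
    tr <- generate_trial(cfg, "AB")
    x <- tr$emg[, 1]
    sp <- Mod(stats::fft(x))^2
    freqs <- (seq_along(x) - 1) * cfg$fs / length(x)
    # mains power concentrates in the exact 60 Hz bin (integer cycles per
    # 5 s trial); compare it with the broadband level nearby
    line <- sp[which.min(abs(freqs - 60))]
    neighbourhood <- mean(sp[(freqs > 50 & freqs < 58) |
                               (freqs > 62 & freqs < 70)])
    line / neighbourhood
  }
  expect_gt(peak_at_60(0.05), 10)
  expect_lt(peak_at_60(0), 3)
})

test_that("generator config rejects malformed inputs", {
  expect_error(generator_config(trials_per_class = 2), "\\[3, 6\\]")
  expect_error(generator_config(synergy_coupling = -0.1), "\\[0, 1\\]")
  bad <- default_torque_directions()
  bad["AB", ] <- c(1, 5, 0, 0)    # dominated by the wrong axis
  expect_error(generator_config(torque_direction_matrix = bad), "dominated")
  expect_error(generator_config(envelope_ramp = 3, envelope_hold = 0),
               "ramp")
})
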