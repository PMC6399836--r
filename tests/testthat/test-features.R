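test_that("window starts follow the 200 ms / 25 ms overlapped scheme", {
  expect_equal(window_starts(200, 200, 25), 1L)
  expect_equal(window_starts(199, 200, 25), integer(0))
  expect_length(window_starts(5000, 200, 25), 193)
  # brute-force enumeration oracle on random lengths
  set.seed(23)
  for (len in sample(0:1200, 40)) {
    w <- sample(1:300, 1); inc <- sample(1:100, 1)
    brute <- Filter(function(s) s + w - 1 <= len, seq_len(max(len, 1)))
    brute <- brute[(brute - 1) %% inc == 0]
    expect_equal(window_starts(len, w, inc), as.integer(brute))
  }
  expect_error(window_starts(100, 0, 25), "> 0")
})

test_that("Hudgins time-domain features match hand-worked values", {
  expect_equal(mav(rep(2, 10)), 2)
  expect_equal(mav(rep(-2, 10)), 2)
  expect_equal(mav(c(1, -3, 2, 0)), 1.5)
  expect_error(mav(numeric(0)), "empty")

  expect_equal(zero_crossings(rep(3, 10)), 0)
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(c(0.01, -0.01, 0.01), deadband = 0.1), 0)
  # zeros count as positive: no crossing created by zeros alone
  expect_equal(zero_crossings(c(0, 0, 0, 1)), 0)
  expect_equal(zero_crossings(c(-1, 0, 1)), 1)
  expect_error(zero_crossings(1:3, deadband = -1), ">= 0")

  expect_equal(slope_sign_changes(seq(0, 1, length.out = 50)), 0)
  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0)), 3)
  # five full sine periods: two extrema per period
  t <- seq(0, 5, length.out = 5000)
  expect_equal(slope_sign_changes(sin(2 * pi * t)), 10)
  expect_error(slope_sign_changes(c(1, 2)), "3 samples")

  expect_equal(waveform_length(rep(4, 7)), 0)
  expect_equal(waveform_length(seq(0, 1, length.out = 23)), 1)
  expect_equal(waveform_length(c(0, 2, -1)), 5)
  expect_error(waveform_length(3), "2 samples")
})

test_that("MAV/WL scale with amplitude; ZC/SSC are amplitude-invariant", {
  set.seed(41)
  x <- rnorm(300)
  for (a in c(0.1, 3, 20)) {
    expect_equal(mav(a * x), a * mav(x))
    expect_equal(waveform_length(a * x), a * waveform_length(x))
    expect_equal(zero_crossings(a * x), zero_crossings(x))
    expect_equal(slope_sign_changes(a * x), slope_sign_changes(x))
  }
})

make_trial_mats <- function(n = 1000, seed = 7) {
  set.seed(seed)
  list(emg = matrix(rnorm(n * 8), n, 8,
                    dimnames = list(NULL, paste0("m", 1:8))),
       lc = matrix(rnorm(n * 6), n, 6,
                   dimnames = list(NULL, c("fx", "fy", "fz", "mx", "my", "mz"))),
       tq = matrix(rnorm(n * 4), n, 4,
                   dimnames = list(NULL, torque_dof_names())))
}

test_that("feature-set dimensionalities are exact for all inputs", {
  expect_equal(feature_set_dim("EMG_TD"), 32L)
  expect_equal(feature_set_dim("LOADCELL"), 6L)
  expect_equal(feature_set_dim("TORQUE"), 4L)
  expect_equal(feature_set_dim("EMG_LC"), 38L)
  m <- make_trial_mats()
  seg <- data.frame(start = 1L, end = 1000L)
  for (fs_name in c("EMG_TD", "LOADCELL", "TORQUE", "EMG_LC")) {
    f <- extract_features(m$emg, m$lc, m$tq, seg, fs_name, fs = 1000,
                          label = "AB", trial_id = "t1")
    expect_equal(ncol(f$values), feature_set_dim(fs_name))
    expect_equal(nrow(f$values), 33)  # (1000 - 200)/25 + 1
    expect_true(all(is.finite(f$values)))
    expect_true(all(f$labels == "AB"))
  }
})

test_that("windows are built per run and counts match brute force", {
  m <- make_trial_mats()
  seg <- data.frame(start = c(1L, 401L, 930L), end = c(350L, 900L, 1000L))
  f <- extract_features(m$emg, m$lc, m$tq, seg, "TORQUE", fs = 1000)
  # runs of 350, 500, 71 samples -> 7 + 13 + 0 windows of 200 @ 25
  expect_equal(nrow(f$values), 7 + 13 + 0)
  # empty segment list is zero rows, not an error
  f0 <- extract_features(m$emg, m$lc, m$tq,
                         data.frame(start = integer(0), end = integer(0)),
                         "EMG_TD", fs = 1000)
  expect_equal(nrow(f0$values), 0)
  expect_equal(ncol(f0$values), 32)
})

test_that("combined features are the bitwise concatenation of their parts", {
  m <- make_trial_mats(seed = 19)
  seg <- data.frame(start = 1L, end = 1000L)
  td <- extract_features(m$emg, m$lc, m$tq, seg, "EMG_TD", fs = 1000)
  lc <- extract_features(m$emg, m$lc, m$tq, seg, "LOADCELL", fs = 1000)
  both <- extract_features(m$emg, m$lc, m$tq, seg, "EMG_LC", fs = 1000)
  expect_identical(unname(both$values),
                   unname(cbind(td$values, lc$values)))
})

test_that("load-cell and torque features are per-channel window means", {
  n <- 400
  lc <- matrix(rep(1:6, each = n), n, 6,
               dimnames = list(NULL, c("fx", "fy", "fz", "mx", "my", "mz")))
  m <- make_trial_mats(n)
  f <- extract_features(m$emg, lc, m$tq, data.frame(start = 1L, end = n),
                        "LOADCELL", fs = 1000)
  expect_true(all(apply(f$values, 1, function(r) all(r == 1:6))))
  # torque means against a direct computation on one window
  f_tq <- extract_features(m$emg, lc, m$tq, data.frame(start = 1L, end = n),
                           "TORQUE", fs = 1000)
  expect_equal(unname(f_tq$values[1, ]), unname(colMeans(m$tq[1:200, ])))
  expect_equal(unname(f_tq$values[2, ]), unname(colMeans(m$tq[26:225, ])))
})

test_that("windowed Hudgins features agree with the scalar implementations", {
  m <- make_trial_mats(seed = 57)
  seg <- data.frame(start = 5L, end = 604L)
  f <- extract_features(m$emg, m$lc, m$tq, seg, "EMG_TD", fs = 1000,
                        deadband = 0.05)
  starts <- 5L + window_starts(600, 200, 25) - 1L
  for (wi in c(1, 8, length(starts))) {
    win <- starts[wi]:(starts[wi] + 199)
    for (ch in c(1, 4, 8)) {
      x <- m$emg[win, ch]
      got <- f$values[wi, (ch - 1) * 4 + 1:4]
      expect_equal(unname(got),
                   c(mav(x), zero_crossings(x, 0.05),
                     slope_sign_changes(x, 0.05), waveform_length(x)))
    }
  }
})
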