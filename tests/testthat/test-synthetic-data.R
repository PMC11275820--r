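test_that("uncoupled channels are uncorrelated across lags", {
  sp <- var_spec(3, 1, seed = 2)
  x <- simulate_var(sp, 4000)
  cors <- c()
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    for (lag in 1:2) {
      n <- nrow(x)
      cors <- c(cors, cor(x[1:(n - lag), i], x[(1 + lag):n, j]))
    }
  }
  expect_gt(mean(abs(cors) <= 2 / sqrt(4000)), 0.9)
})

test_that("lag-1 coupling reproduces the closed-form cross-moment", {
  # y_t = 0.9 x_{t-1} + eps => corr(x_{t-1}, y_t) = 0.9 / sqrt(1 + 0.81)
  sp <- var_spec(2, 1, coupling = data.frame(source = 1, target = 2,
                                             lag = 1, coefficient = 0.9),
                 seed = 7)
  x <- simulate_var(sp, 2000)
  sample_corr <- cor(x[-2000, 1], x[-1, 2])  # brute-force sample moment
  expect_equal(sample_corr, 0.9 / sqrt(1.81), tolerance = 0.05)
})

test_that("simulation is a pure function of spec and seed", {
  sp <- var_spec(3, 2, coupling = data.frame(source = 1, target = 2,
                                             lag = 2, coefficient = 0.4),
                 seed = 11)
  expect_identical(simulate_var(sp, 300), simulate_var(sp, 300))
  expect_false(identical(simulate_var(sp, 300),
                         simulate_var(sp, 300, seed = 12)))
})

test_that("non-stationary and undersized requests are rejected", {
  expect_error(var_spec(1, 1, coupling = data.frame(source = 1, target = 1,
                                                    lag = 1,
                                                    coefficient = 1.05)),
               "non-stationary")
  sp <- var_spec(2, 3, seed = 1)
  expect_error(simulate_var(sp, 25), "must exceed")
})

test_that("session segmentation arithmetic matches the trial structure", {
  spec <- session_spec(n_subjects = 2, n_trials_per_subject = 3,
                       trial_duration_s = 63, baseline_duration_s = 3,
                       sampling_rate_hz = 16, n_channels = 2, n_classes = 2,
                       seed = 1)
  ses <- simulate_session(spec)
  counts <- dplyr::count(ses$meta, subject, video)
  expect_true(all(counts$n == 60))
  expect_equal(nrow(ses$meta), 2 * 3 * 60)
  expect_equal(dim(ses$segments), c(360, 16, 2))
  # video -> class assignment is shared across subjects
  by_video <- dplyr::distinct(ses$meta, video, class)
  expect_equal(nrow(by_video), 3)
})

test_that("a signal-free trial yields all-zero segments after baseline removal", {
  profiles <- list(list(freqs_hz = numeric(), amps = matrix(0, 2, 0)),
                   list(freqs_hz = numeric(), amps = matrix(0, 2, 0)))
  spec <- session_spec(n_subjects = 1, n_trials_per_subject = 2,
                       trial_duration_s = 5, baseline_duration_s = 3,
                       sampling_rate_hz = 8, n_channels = 2, n_classes = 2,
                       class_band_powers = profiles, noise_sd = 0, seed = 1)
  ses <- simulate_session(spec)
  expect_equal(max(abs(ses$segments)), 0)
})

test_that("class oscillations are evoked, not cancelled by baseline removal", {
  spec <- session_spec(n_subjects = 1, n_trials_per_subject = 2,
                       trial_duration_s = 6, baseline_duration_s = 3,
                       sampling_rate_hz = 32, n_channels = 4, n_classes = 2,
                       noise_sd = 0, seed = 3)
  ses <- simulate_session(spec)
  expect_gt(sd(ses$segments), 0.1)
})

test_that("tonal signals have the expected RMS and spectrum", {
  x <- tonal_signal(10, 1, 4096, 128, noise_sd = 0)
  expect_equal(sqrt(mean(x^2)), 1 / sqrt(2), tolerance = 0.01)

  w <- tonal_signal(numeric(), numeric(), 4000, 128, noise_sd = 1, seed = 4)
  expect_equal(sd(w), 1, tolerance = 0.05)

  y <- tonal_signal(c(5, 12, 30), c(1, 1, 1), 128, 128, noise_sd = 0)
  amp <- oracle_dft_amplitude(y)
  top3 <- order(-amp)[1:3] - 1  # bin index = frequency in Hz here
  expect_setequal(top3, c(5, 12, 30))

  expect_error(tonal_signal(70, 1, 128, 128), "Nyquist")
  expect_error(tonal_signal(c(5, 10), 1, 128, 128), "equal length")
})

test_that("sessions survive a plain-text write/read round trip", {
  ses <- tiny_session(seed = 9, n_videos = 2)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$segments, ses$segments, tolerance = 1e-12)
  expect_equal(back$meta$class, ses$meta$class)
})
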