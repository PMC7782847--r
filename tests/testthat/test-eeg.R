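test_that("the zero-phase bandpass meets its passband/stopband contract", {
  fs <- 256
  t <- (0:(6 * fs - 1)) / fs
  core <- (2 * fs):(4 * fs)
  g13 <- max(abs(eeg_bandpass(sin(2 * pi * 13 * t), fs, 11, 16)[core]))
  expect_gte(g13, 0.95)
  # one octave below the low edge: at least 20 dB down
  g5.5 <- max(abs(eeg_bandpass(sin(2 * pi * 5.5 * t), fs, 11, 16)[core]))
  expect_lte(g5.5, 0.1)
  expect_equal(eeg_bandpass(rep(0, fs), fs, 11, 16), rep(0, fs))
  # zero phase: a passband sinusoid is not shifted
  y <- eeg_bandpass(sin(2 * pi * 13 * t), fs, 11, 16)
  expect_gt(cor(y[core], sin(2 * pi * 13 * t)[core]), 0.999)
  expect_error(eeg_bandpass(rnorm(100), 100, 11, 60), "fs/2")
})

test_that("cue-locked spectrograms use the declared grid and find tones", {
  fs <- 256
  rec <- structure(list(samples = rep(0, fs * 30), fs = fs,
                        events = NULL), class = "eeg_recording")
  tf <- epoch_and_spectrogram(rec, c(5, 12))
  expect_equal(dim(tf$power)[1], 2L)
  expect_equal(length(tf$freqs), 100L)
  expect_equal(tf$freqs[1], 0.25)
  expect_equal(diff(tf$times)[1], 0.0625)  # 87.5% overlap of 500 ms
  expect_true(all(tf$power == 0))

  t <- (0:(fs * 30 - 1)) / fs
  rec$samples <- sin(2 * pi * 10 * t)
  tf2 <- epoch_and_spectrogram(rec, c(5, 12))
  peak <- tf2$freqs[which.max(apply(tf2$power[1, , ], 1, mean))]
  expect_equal(peak, 10)

  expect_warning(tf3 <- epoch_and_spectrogram(rec, c(0.2, 12)), "truncated")
  expect_equal(dim(tf3$power)[1], 1L)
})

test_that("baseline correction is exact and invertible", {
  times <- seq(-0.25, 3.75, by = 0.0625)
  m <- matrix(5, nrow = 10, ncol = length(times))
  corr <- baseline_correct(m, times)
  expect_true(all(corr == 0))
  m2 <- m; m2[, times > 0] <- 10
  corr2 <- baseline_correct(m2, times)
  expect_true(all(corr2[, times > 0] == 100))
  # un-correct with the stored baseline recovers the original matrix
  base <- rowMeans(m2[, times >= -0.5 & times <= -0.2, drop = FALSE])
  back <- corr2 / 100 * base + base
  expect_equal(back, m2)
  expect_error(baseline_correct(matrix(0, 2, length(times)), times), "zero baseline")
})

test_that("t-map clustering recovers an injected blob and rejects zeros", {
  expect_equal(length(cluster_tmap(array(0, c(5, 8, 8)), 1:8, 1:8)), 0L)
  set.seed(41)
  freqs <- seq(0.25, 25, by = 0.25); times <- seq(-0.25, 3.75, by = 0.0625)
  nf <- length(freqs); nt <- length(times)
  arr <- array(rnorm(12 * nf * nt), c(12, nf, nt))
  fsel <- freqs >= 12 & freqs <= 15
  tsel <- times >= 1.0 & times <= 1.4
  arr[, fsel, tsel] <- arr[, fsel, tsel] + 8
  cl <- cluster_tmap(arr, times, freqs)
  expect_equal(length(cl), 1L)
  expect_lte(cl[[1]]$freq_range[1], 12)
  expect_gte(cl[[1]]$freq_range[2], 15)
  expect_lte(cl[[1]]$time_range[1], 1.0)
  expect_gte(cl[[1]]$time_range[2], max(times[tsel]) - 1e-9)
  expect_equal(cl[[1]]$sign, 1)

  m <- matrix(10, nf, nt)
  expect_equal(cluster_power(m, cl[[1]]), 10)
  single <- cl[[1]]; single$mask[] <- FALSE; single$mask[40, 25] <- TRUE
  m[40, 25] <- -3.5
  expect_equal(cluster_power(m, single), -3.5)
  chk <- cl[[1]]
  m2 <- matrix(0, nf, nt)
  m2[chk$mask] <- rep_len(c(1, -1), chk$n_points)  # alternating over members
  expect_equal(cluster_power(m2, chk),
               mean(rep_len(c(1, -1), chk$n_points)))
  empty <- cl[[1]]; empty$mask[] <- FALSE
  expect_error(cluster_power(m, empty), "empty")
})

test_that("the RMS detector finds bursts inside its duration window only", {
  fs <- 256
  expect_equal(nrow(detect_spindles(rep(0, fs * 30), fs)), 0L)
  # sigma-band background at unit RMS plus a Hann-enveloped 13 Hz burst
  make_rec <- function(seed, dur_s, amp = 8) {
    set.seed(seed)
    bed <- eeg_bandpass(rnorm(fs * 60, 0, 5), fs, 11, 16)
    bed <- bed / sd(bed)
    n <- round(dur_s * fs); tt <- (0:(n - 1)) / fs
    burst <- amp * sin(2 * pi * 13 * tt) *
      0.5 * (1 - cos(2 * pi * seq_len(n) / n))
    bed[(20 * fs):(20 * fs + n - 1)] <- bed[(20 * fs):(20 * fs + n - 1)] + burst
    bed
  }
  x <- make_rec(1, 1.0)
  ev <- detect_spindles(x, fs)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 20), 0.35)
  expect_true(ev$duration_s >= 0.5 && ev$duration_s <= 3)
  expect_gt(ev$peak_amp_uv, 4)

  # the same burst compressed to 0.4 s falls below the minimum duration
  expect_equal(nrow(detect_spindles(make_rec(1, 0.4), fs)), 0L)

  # events never overlap the exclusion mask
  mask <- rep(FALSE, length(x)); mask[(20 * fs):(21 * fs)] <- TRUE
  ev2 <- detect_spindles(x, fs, exclusion_mask = mask)
  expect_equal(nrow(ev2), 0L)
  expect_error(detect_spindles(x, fs, exclusion_mask = rep(TRUE, length(x))),
               "excluded")
})

test_that("spindle probability timecourses are baseline-referenced fractions", {
  none <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     peak_amp_uv = numeric(0))
  res <- spindle_probability_timecourse(none, c(10, 20), c(1, 6))
  expect_true(all(res$traces == 0))

  # a spindle covering [1, 1.5] s after every cue, nothing in the baseline
  cues <- c(10, 20, 30)
  sp <- data.frame(onset_s = cues + 1, duration_s = 0.5, peak_amp_uv = 30)
  res2 <- spindle_probability_timecourse(sp, cues, c(1, 2, 6),
                                         cluster_window = c(0.9, 1.6))
  inwin <- res2$times >= 1.05 & res2$times <= 1.45
  expect_true(all(res2$traces[, inwin] == 1))
  expect_true(all(res2$raw_traces[, res2$times < 0.5] == 0))
  expect_true(all(res2$trials$spindle_in_cluster))
  expect_equal(res2$trials$max_amp_uv, rep(30, 3))
})

test_that("the set-size mixed model recovers known slopes", {
  set.seed(43)
  make_trials <- function(slope, n_subj = 10, n_per = 40, subj_sd = 1) {
    k <- sample(c(0, 1, 2, 6), n_subj * n_per, TRUE)
    subj <- rep(paste0("s", 1:n_subj), each = n_per)
    snd <- paste0("snd", k, "_", sample(1:3, n_subj * n_per, TRUE))
    u <- rnorm(n_subj, 0, subj_sd)[as.integer(factor(subj))]
    data.frame(response = 2 + u + slope * k + rnorm(n_subj * n_per),
               size_k = k, participant_id = subj, sound_id = snd)
  }
  fit <- fit_setsize_lmm(make_trials(2))
  expect_equal(fit$estimate, 2, tolerance = 0.15)
  expect_true(fit$ci[1] < 2 & fit$ci[2] > 2)
  expect_lt(fit$p, 1e-6)

  null_fit <- fit_setsize_lmm(make_trials(0))
  expect_gt(null_fit$p, 0.001)

  # single participant: degenerate structure reduces to the OLS slope
  one <- make_trials(1.5, n_subj = 1, n_per = 120)
  f1 <- fit_setsize_lmm(one)
  expect_equal(f1$estimate, unname(coef(lm(response ~ size_k, one))[2]),
               tolerance = 1e-6)
})

test_that("the memory-physiology mixed model recovers the coupling", {
  set.seed(44)
  n_subj <- 12; n_per <- 30
  subj <- rep(paste0("s", 1:n_subj), each = n_per)
  mod <- rnorm(n_subj * n_per, 10, 4)
  k <- sample(c(1, 2, 6), n_subj * n_per, TRUE)
  dat <- data.frame(benefit = 0.5 * mod + rnorm(n_subj * n_per, 0, 1),
                    modulation = mod, size_k = k, participant_id = subj)
  fit <- fit_memory_physiology_lmm(dat)
  expect_equal(fit$modulation$estimate, 0.5, tolerance = 0.1)
  expect_lt(fit$modulation$p, 1e-4)

  dat$modulation <- 3
  expect_error(fit_memory_physiology_lmm(dat), "constant modulation")
  expect_error(fit_memory_physiology_lmm(dat[0, ]), "empty")
})
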