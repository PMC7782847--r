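#' Synthesize NREM-like background EEG
#'
#' A 1/f^alpha-shaped Gaussian noise bed (spectral shaping in the Fourier
#' domain, scaled to a target RMS) plus a continuous slow oscillation,
#' zero-mean. This emulates the stationary statistics of single-channel
#' NREM sleep away from cue events; it does not model staging transitions,
#' K-complex morphology, or arousals.
#'
#' @param duration_s Recording length, seconds (> 0).
#' @param fs Sampling rate, Hz (>= 128 so the 25 Hz analysis band is well
#'   below Nyquist).
#' @param noise_rms_uv RMS amplitude of the 1/f noise bed, microvolts.
#' @param alpha Spectral exponent of the noise bed.
#' @param slow_amp_uv Amplitude of the continuous slow oscillation.
#' @param slow_freq_hz Slow-oscillation frequency.
#' @param rng_seed Optional integer seed.
#' @return An `eeg_recording`: list with `samples` (microvolts), `fs`, and
#'   an empty `events` data frame.
#' @export
synthesize_background <- function(duration_s, fs = 512, noise_rms_uv = 15,
                                  alpha = 1.5, slow_amp_uv = 20,
                                  slow_freq_hz = 0.8, rng_seed = NULL) {
  stopifnot(duration_s > 0)
  if (fs < 128) stop("fs must be at least 128 Hz")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- round(duration_s * fs)
  if (noise_rms_uv > 0) {
    w <- stats::rnorm(n)
    f <- stats::fft(w)
    freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
    shape <- c(0, freqs[-1]^(-alpha / 2))
    x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    x <- x * noise_rms_uv / stats::sd(x)
  } else x <- numeric(n)
  if (slow_amp_uv > 0) {
    t <- (seq_len(n) - 1) / fs
    x <- x + slow_amp_uv * sin(2 * pi * slow_freq_hz * t + stats::runif(1, 0, 2 * pi))
    x <- x - mean(x)
  }
  structure(list(samples = x, fs = fs,
                 events = data.frame(sound_id = character(0),
                                     size_k = integer(0),
                                     onset_s = numeric(0))),
            class = "eeg_recording")
}

#' Parameters of the cue-evoked responses
#'
#' Ground-truth linear set-size modulation the analysis stack must recover:
#' every cue evokes a delta-theta burst with amplitude
#' `deltatheta_amp_base + deltatheta_amp_per_item * k`, and with probability
#' `spindle_prob_base + spindle_prob_per_item * k` (clipped to `[0, 1]`) a
#' sleep spindle is added. The novel sound has `k = 0`.
#'
#' @param spindle_prob_base Spindle probability intercept per cue.
#' @param spindle_prob_per_item Spindle probability increment per item.
#' @param spindle_amp_uv Spindle peak amplitude, microvolts.
#' @param spindle_freq_range Spindle frequency range, Hz.
#' @param spindle_duration_range Spindle duration range, seconds (inside the
#'   detector's 0.5-3 s window).
#' @param spindle_latency_window Spindle onset window after cue onset, s.
#' @param deltatheta_amp_base Delta-theta burst amplitude intercept.
#' @param deltatheta_amp_per_item Delta-theta amplitude increment per item.
#' @param deltatheta_freq_range Burst frequency range, Hz.
#' @param deltatheta_latency_window Burst onset window after cue onset, s.
#' @param deltatheta_duration_s Burst duration, seconds.
#' @return An `evoked_params` object (list).
#' @export
evoked_response_params <- function(spindle_prob_base = 0.2,
                                   spindle_prob_per_item = 0.05,
                                   spindle_amp_uv = 25,
                                   spindle_freq_range = c(11, 16),
                                   spindle_duration_range = c(0.9, 1.8),
                                   spindle_latency_window = c(0.7, 1.3),
                                   deltatheta_amp_base = 30,
                                   deltatheta_amp_per_item = 4,
                                   deltatheta_freq_range = c(2, 6),
                                   deltatheta_latency_window = c(0.25, 0.45),
                                   deltatheta_duration_s = 0.5) {
  stopifnot(spindle_duration_range[1] >= 0.5, spindle_duration_range[2] <= 3)
  structure(as.list(environment()), class = "evoked_params")
}

# add a Hann-enveloped sinusoid in place
.add_burst <- function(x, fs, onset_s, duration_s, freq_hz, amp_uv, phase) {
  i0 <- round(onset_s * fs) + 1L
  len <- round(duration_s * fs)
  i1 <- min(i0 + len - 1L, length(x))
  if (i1 < i0) return(x)
  idx <- i0:i1
  tt <- (idx - i0) / fs
  env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (len + 1)))
  x[idx] <- x[idx] + amp_uv * env * sin(2 * pi * freq_hz * tt + phase)
  x
}

#' Inject cue-evoked delta-theta bursts and probabilistic spindles
#'
#' @param recording An `eeg_recording` from [synthesize_background()].
#' @param schedule Cue schedule data frame with `sound_id`, `size_k`,
#'   `onset_s` (all onsets must fall inside the recording).
#' @param params An [evoked_response_params()].
#' @param rng_seed Optional integer seed.
#' @return List: `recording` (with events attached) and `truth`, a ground
#'   truth data frame of injected spindles (`trial`, `sound_id`, `size_k`,
#'   `onset_s`, `duration_s`, `freq_hz`, `amp_uv`).
#' @export
inject_cue_responses <- function(recording, schedule,
                                 params = evoked_response_params(),
                                 rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x <- recording$samples; fs <- recording$fs
  dur <- length(x) / fs
  if (any(schedule$onset_s < 0 | schedule$onset_s > dur - 4))
    stop("cue onsets must leave room for a full post-cue epoch")
  truth <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    k <- schedule$size_k[i]
    on <- schedule$onset_s[i]
    dt_amp <- params$deltatheta_amp_base + params$deltatheta_amp_per_item * k
    x <- .add_burst(x, fs,
                    on + stats::runif(1, params$deltatheta_latency_window[1],
                                      params$deltatheta_latency_window[2]),
                    params$deltatheta_duration_s,
                    stats::runif(1, params$deltatheta_freq_range[1],
                                 params$deltatheta_freq_range[2]),
                    dt_amp, stats::runif(1, 0, 2 * pi))
    p_sp <- min(1, max(0, params$spindle_prob_base +
                         params$spindle_prob_per_item * k))
    if (stats::runif(1) < p_sp) {
      sp_on <- on + stats::runif(1, params$spindle_latency_window[1],
                                 params$spindle_latency_window[2])
      sp_dur <- stats::runif(1, params$spindle_duration_range[1],
                             params$spindle_duration_range[2])
      sp_f <- stats::runif(1, params$spindle_freq_range[1],
                           params$spindle_freq_range[2])
      x <- .add_burst(x, fs, sp_on, sp_dur, sp_f, params$spindle_amp_uv,
                      stats::runif(1, 0, 2 * pi))
      truth[[i]] <- data.frame(trial = i, sound_id = schedule$sound_id[i],
                               size_k = k, onset_s = sp_on,
                               duration_s = sp_dur, freq_hz = sp_f,
                               amp_uv = params$spindle_amp_uv)
    }
  }
  recording$samples <- x
  recording$events <- schedule[, c("sound_id", "size_k", "onset_s")]
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth))
    truth <- data.frame(trial = integer(0), sound_id = character(0),
                        size_k = integer(0), onset_s = numeric(0),
                        duration_s = numeric(0), freq_hz = numeric(0),
                        amp_uv = numeric(0))
  list(recording = recording, truth = truth)
}

#' Write / read a recording as raw float binary plus JSON sidecar
#'
#' Samples are stored as little-endian 32-bit floats; sampling rate, units,
#' and the event table live in a JSON sidecar next to the binary file.
#'
#' @param recording An `eeg_recording`.
#' @param path Path of the binary file (`.bin`); the sidecar gets `.json`.
#' @return `write_recording()` invisibly returns the two paths;
#'   `read_recording()` returns the `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$samples), con, size = 4, endian = "little")
  sidecar <- sub("\\.bin$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(fs = recording$fs, units = "uV",
                            n_samples = length(recording$samples),
                            events = recording$events),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- sub("\\.bin$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_samples, size = 4, endian = "little")
  ev <- as.data.frame(meta$events)
  structure(list(samples = x, fs = meta$fs, events = ev),
            class = "eeg_recording")
}
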