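#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc FIR design (`signal::fir1`) applied as a single symmetric
#' (linear-phase) kernel with the group delay compensated, so the net filter
#' has zero phase shift. The order is sized from the transition width: a
#' narrow transition keeps in-band sinusoids above 95% amplitude while a
#' tone one octave outside the band is attenuated by more than 20 dB.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param lo_hz,hi_hz Band edges; must satisfy `0 < lo < hi < fs/2`.
#' @param transition_hz Target transition bandwidth; defaults to the smaller
#'   of 2 Hz and half the lower band edge.
#' @param order FIR order (even); default `round(3.3 * fs / transition_hz)`
#'   (the Hamming-window design rule).
#' @return Filtered signal, same length.
#' @export
eeg_bandpass <- function(x, fs, lo_hz, hi_hz, transition_hz = NULL,
                         order = NULL) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2))
    stop("need 0 < lo_hz < hi_hz < fs/2")
  if (is.null(transition_hz)) transition_hz <- min(2, lo_hz / 2)
  if (is.null(order)) order <- round(3.3 * fs / transition_hz)
  order <- max(16L, min(as.integer(order), 8192L))
  if (order %% 2L == 1L) order <- order + 1L
  flt <- as.numeric(signal::fir1(order, c(lo_hz, hi_hz) / (fs / 2),
                                 type = "pass"))
  h <- order %/% 2L
  padded <- c(rep(0, h), x, rep(0, h))
  y <- stats::filter(padded, flt, method = "convolution", sides = 2)
  as.numeric(y[(h + 1L):(h + length(x))])
}

#' Cue-locked epoching and short-time Fourier spectrograms
#'
#' Extracts an epoch around every cue onset, subtracts the epoch mean, and
#' computes power on a fixed time-frequency grid: 0.25-25 Hz in 0.25 Hz
#' steps (100 bins) from a 500-ms Hamming-windowed sliding segment with
#' 87.5% overlap (62.5-ms hop). Frequencies are evaluated directly on the
#' declared grid (Goertzel-style complex-exponential projection), as the
#' 0.25-Hz spacing is finer than the natural resolution of a 500-ms window.
#' Epochs that would be truncated by the recording edges are dropped with a
#' warning.
#'
#' @param recording An `eeg_recording`.
#' @param onsets_s Cue onset times, seconds.
#' @param epoch_window Epoch bounds relative to onset, seconds.
#' @param window_s STFT segment length, seconds.
#' @param overlap_frac STFT segment overlap fraction.
#' @param freqs Frequency grid, Hz.
#' @return List (`tf_epochs`): `power` (array trial x freq x time), `times`
#'   (segment centres relative to onset), `freqs`, `kept` (indices of
#'   retained onsets).
#' @export
epoch_and_spectrogram <- function(recording, onsets_s,
                                  epoch_window = c(-0.5, 4),
                                  window_s = 0.5, overlap_frac = 0.875,
                                  freqs = seq(0.25, 25, by = 0.25)) {
  fs <- recording$fs
  x <- recording$samples
  wl <- round(window_s * fs)
  hop <- round(wl * (1 - overlap_frac))
  ep_len <- round((epoch_window[2] - epoch_window[1]) * fs)
  starts <- round((onsets_s + epoch_window[1]) * fs) + 1L
  ok <- starts >= 1L & (starts + ep_len - 1L) <= length(x)
  if (!all(ok)) warning(sum(!ok), " truncated epoch(s) dropped")
  starts <- starts[ok]
  if (!length(starts)) stop("no complete epochs")
  seg_starts <- seq(1L, ep_len - wl + 1L, by = hop)
  times <- epoch_window[1] + (seg_starts - 1L + wl / 2) / fs
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, wl - 1) / (wl - 1))  # Hamming
  tt <- (seq_len(wl) - 1) / fs
  E <- exp(-2i * pi * outer(freqs, tt))      # nfreq x wl projection matrix
  Ew <- E * rep(win, each = length(freqs))
  pow <- array(NA_real_, c(length(starts), length(freqs), length(seg_starts)))
  seg_idx <- outer(seq_len(wl) - 1L, seg_starts, "+")  # wl x nseg
  for (tr in seq_along(starts)) {
    ep <- x[starts[tr] + seq_len(ep_len) - 1L]
    ep <- ep - mean(ep)
    segs <- matrix(ep[seg_idx], nrow = wl)
    pow[tr, , ] <- Mod(Ew %*% segs)^2
  }
  structure(list(power = pow, times = times, freqs = freqs,
                 kept = which(ok)), class = "tf_epochs")
}

#' Baseline correction to percent power change
#'
#' Per frequency, converts power to percent change relative to the mean over
#' the baseline window: `100 * (P(t, f) - B(f)) / B(f)`.
#'
#' @param power Matrix (freq x time) or array (trial x freq x time).
#' @param times Time axis matching the last dimension, seconds.
#' @param baseline_window Baseline bounds, seconds (default the 300-ms
#'   interval starting 500 ms before cue onset).
#' @param baseline Optional precomputed per-frequency baseline vector
#'   (overrides the window; used to undo/redo corrections).
#' @return Same shape as `power`, in percent change.
#' @export
baseline_correct <- function(power, times, baseline_window = c(-0.5, -0.2),
                             baseline = NULL) {
  bcols <- which(times >= baseline_window[1] & times <= baseline_window[2])
  correct_mat <- function(m) {
    b <- if (is.null(baseline)) rowMeans(m[, bcols, drop = FALSE]) else baseline
    if (any(b == 0)) stop("zero baseline power at some frequency")
    100 * (m - b) / b
  }
  if (length(dim(power)) == 2L) return(correct_mat(power))
  if (!length(bcols) && is.null(baseline)) stop("baseline window not covered")
  out <- power
  for (tr in seq_len(dim(power)[1])) out[tr, , ] <- correct_mat(power[tr, , ])
  out
}

# connected components of a logical matrix under 8- or 4-connectivity
.connected_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nrow(mask) + 1L
      j <- (cur - 1L) %/% nrow(mask) + 1L
      ni <- i + offs[, 1]; nj <- j + offs[, 2]
      keep <- ni >= 1 & ni <= nrow(mask) & nj >= 1 & nj <= ncol(mask)
      lin <- (nj[keep] - 1L) * nrow(mask) + ni[keep]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nxt
      queue <- c(queue, lin)
    }
  }
  lab
}

#' Bonferroni-thresholded time-frequency clusters
#'
#' One-sample t-test against zero at every time-frequency point across
#' participants; points with two-sided `p < alpha / n_points` (Bonferroni
#' over the grid) are kept and grouped into connected components
#' (8-connectivity by default). Each cluster is reported with its bounding
#' time and frequency ranges.
#'
#' @param corrected Array (participant x freq x time) of baseline-corrected
#'   percent power change.
#' @param times,freqs Grid axes.
#' @param alpha Per-comparison significance level before correction.
#' @param connectivity 8 or 4.
#' @return List of `tf_cluster`s, each with `mask` (freq x time logical),
#'   `freq_range`, `time_range`, `n_points`, `sign` (sign of the mean t in
#'   the cluster). Empty list if nothing crosses the threshold.
#' @export
cluster_tmap <- function(corrected, times, freqs, alpha = 0.001,
                         connectivity = 8L) {
  n <- dim(corrected)[1]
  if (n < 3) stop("need at least 3 participants")
  mu <- apply(corrected, c(2, 3), mean)
  sdv <- apply(corrected, c(2, 3), stats::sd)
  tmap <- mu / (sdv / sqrt(n))
  tmap[sdv == 0] <- 0
  p <- 2 * stats::pt(abs(tmap), n - 1, lower.tail = FALSE)
  thr <- alpha / length(p)
  mask <- p < thr
  if (!any(mask)) return(list())
  lab <- .connected_components(mask, connectivity)
  lapply(seq_len(max(lab)), function(id) {
    m <- lab == id
    ij <- which(m, arr.ind = TRUE)
    structure(list(mask = m,
                   freq_range = range(freqs[ij[, 1]]),
                   time_range = range(times[ij[, 2]]),
                   n_points = nrow(ij),
                   sign = sign(mean(tmap[m]))), class = "tf_cluster")
  })
}

#' Mean baseline-corrected power over a cluster
#'
#' @param corrected Matrix (freq x time) of corrected power for one trial
#'   (or one participant mean).
#' @param cluster A `tf_cluster` from [cluster_tmap()].
#' @return Scalar mean modulation (percent).
#' @export
cluster_power <- function(corrected, cluster) {
  if (!any(cluster$mask)) stop("empty cluster")
  mean(corrected[cluster$mask])
}

#' Spindle detector configuration
#'
#' @param band Sigma band for filtering, Hz.
#' @param rms_window_s Moving RMS window, seconds (centred; edge samples use
#'   shrinking windows).
#' @param threshold_sd Threshold in SD units above the mean of the RMS
#'   trace.
#' @param min_dur_s,max_dur_s Accepted event duration bounds, seconds.
#' @param sd_basis `"rms"` (SD of the RMS trace, default) or `"signal"`
#'   (SD of the filtered signal).
#' @return A `spindle_detector_config` (list).
#' @export
spindle_detector_config <- function(band = c(11, 16), rms_window_s = 0.2,
                                    threshold_sd = 1.5, min_dur_s = 0.5,
                                    max_dur_s = 3.0,
                                    sd_basis = c("rms", "signal")) {
  stopifnot(min_dur_s < max_dur_s, threshold_sd > 0)
  structure(list(band = band, rms_window_s = rms_window_s,
                 threshold_sd = threshold_sd, min_dur_s = min_dur_s,
                 max_dur_s = max_dur_s, sd_basis = match.arg(sd_basis)),
            class = "spindle_detector_config")
}

# centred moving RMS with shrinking edge windows, via cumulative sums
.moving_rms <- function(x, win) {
  half <- win %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' RMS-threshold sleep spindle detection
#'
#' The signal is bandpass filtered to the sigma band, a centred 200-ms
#' moving RMS is computed at every sample, and maximal runs in which the RMS
#' stays above `mean + 1.5 SD` of the artifact-free RMS trace for 0.5-3 s
#' become spindle events. Each event's peak amplitude is the larger of the
#' highest peak and the absolute lowest trough of the filtered trace within
#' the event. Events overlapping excluded (artifact) samples are discarded.
#'
#' @param x Numeric EEG signal, microvolts.
#' @param fs Sampling rate, Hz.
#' @param config A [spindle_detector_config()].
#' @param exclusion_mask Optional logical vector (`TRUE` = excluded sample).
#' @return Data frame (`spindle_events`): `onset_s`, `duration_s`,
#'   `peak_amp_uv`.
#' @export
detect_spindles <- function(x, fs, config = spindle_detector_config(),
                            exclusion_mask = NULL) {
  if (is.null(exclusion_mask)) exclusion_mask <- rep(FALSE, length(x))
  if (all(exclusion_mask)) stop("all samples are excluded")
  filt <- eeg_bandpass(x, fs, config$band[1], config$band[2])
  rms <- .moving_rms(filt, max(2L, round(config$rms_window_s * fs)))
  inc <- !exclusion_mask
  thr <- if (config$sd_basis == "rms")
    mean(rms[inc]) + config$threshold_sd * stats::sd(rms[inc])
  else config$threshold_sd * stats::sd(filt[inc])
  above <- rms > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_dur_s * fs &
    r$lengths <= config$max_dur_s * fs
  out <- lapply(which(keep), function(i) {
    i0 <- starts[i]; i1 <- ends[i]
    if (any(exclusion_mask[i0:i1])) return(NULL)
    seg <- filt[i0:i1]
    data.frame(onset_s = (i0 - 1) / fs, duration_s = (i1 - i0 + 1) / fs,
               peak_amp_uv = max(max(seg), abs(min(seg))))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_amp_uv = numeric(0))
  out
}

#' Cue-locked spindle probability timecourses
#'
#' For every time point relative to cue onset, the fraction of trials during
#' which a detected spindle is ongoing, baseline-subtracted (mean over the
#' baseline window) and grouped by set size. Also returns a per-trial table
#' with a binary "spindle ongoing inside the sigma-cluster timeframe" flag
#' and the maximum amplitude of spindles starting within the post-cue
#' window.
#'
#' @param spindles Detected events from [detect_spindles()].
#' @param cue_onsets Cue onset times, seconds.
#' @param sizes Set size per cue (0 for the novel sound).
#' @param window Timecourse bounds relative to onset, seconds.
#' @param dt Timecourse resolution, seconds.
#' @param baseline_window Baseline bounds, seconds.
#' @param cluster_window Optional sigma-cluster timeframe for the per-trial
#'   binary flag, seconds.
#' @return List: `times`, `traces` (matrix size-class x time, baseline
#'   subtracted), `raw_traces`, `trials` (per-trial `size_k`,
#'   `spindle_in_cluster`, `max_amp_uv`).
#' @export
spindle_probability_timecourse <- function(spindles, cue_onsets, sizes,
                                           window = c(-0.5, 4), dt = 1 / 64,
                                           baseline_window = c(-0.5, -0.2),
                                           cluster_window = NULL) {
  times <- seq(window[1], window[2], by = dt)
  n_tr <- length(cue_onsets)
  ongoing <- matrix(FALSE, n_tr, length(times))
  in_cluster <- logical(n_tr)
  max_amp <- rep(NA_real_, n_tr)
  sp_end <- spindles$onset_s + spindles$duration_s
  for (i in seq_len(n_tr)) {
    tt <- cue_onsets[i] + times
    for (j in seq_len(nrow(spindles))) {
      hit <- tt >= spindles$onset_s[j] & tt <= sp_end[j]
      if (any(hit)) ongoing[i, hit] <- TRUE
    }
    rel_on <- spindles$onset_s - cue_onsets[i]
    post <- rel_on >= 0 & rel_on <= window[2]
    if (any(post)) max_amp[i] <- max(spindles$peak_amp_uv[post])
    if (!is.null(cluster_window)) {
      cw <- times >= cluster_window[1] & times <= cluster_window[2]
      in_cluster[i] <- any(ongoing[i, cw])
    }
  }
  classes <- sort(unique(sizes))
  bcols <- times >= baseline_window[1] & times <= baseline_window[2]
  raw <- t(vapply(classes, function(k) colMeans(ongoing[sizes == k, , drop = FALSE]),
                  numeric(length(times))))
  rownames(raw) <- classes
  traces <- raw - rowMeans(raw[, bcols, drop = FALSE])
  dropped <- setdiff(unique(sizes), classes[rowSums(!is.na(raw)) > 0])
  if (length(dropped)) warning("size class(es) without trials omitted")
  list(times = times, traces = traces, raw_traces = raw,
       trials = data.frame(size_k = sizes, spindle_in_cluster = in_cluster,
                           max_amp_uv = max_amp))
}

# extract slope results from an lmerMod / lm fit
.slope_report <- function(fit, term, note) {
  if (inherits(fit, "lmerModLmerTest") || inherits(fit, "lmerMod")) {
    co <- stats::coef(summary(fit))
    est <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
    tv <- co[term, "t value"]
    dfv <- if ("df" %in% colnames(co)) co[term, "df"] else NA_real_
    pv <- if ("Pr(>|t|)" %in% colnames(co)) co[term, "Pr(>|t|)"] else
      2 * stats::pnorm(abs(tv), lower.tail = FALSE)
  } else {
    co <- stats::coef(summary(fit))
    est <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
    tv <- co[term, "t value"]; dfv <- fit$df.residual
    pv <- co[term, "Pr(>|t|)"]
  }
  list(estimate = unname(est), se = unname(se),
       ci = unname(est + c(-1, 1) * 1.96 * se),
       t = unname(tv), df = unname(dfv), p = unname(pv), note = note)
}

#' Linear mixed model of set-size modulation
#'
#' Fits `response ~ 1 + size + (1 + size | participant) + (1 | sound)` by
#' maximum likelihood, with set size coded numerically (novel sound = 0).
#' Degenerate random-effect structures are simplified stepwise (drop the
#' random slope, then the sound intercept, then fall back to ordinary least
#' squares) with the simplification recorded in the returned `note`.
#'
#' @param data Data frame with columns `response`, `size_k`,
#'   `participant_id`, `sound_id` (one row per trial).
#' @return List: `estimate` (set-size slope), `se`, `ci` (95% Wald), `t`,
#'   `df`, `p`, `note`.
#' @export
fit_setsize_lmm <- function(data) {
  data$size_k <- as.numeric(data$size_k)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  forms <- list(
    full = response ~ size_k + (1 + size_k | participant_id) + (1 | sound_id),
    no_slope = response ~ size_k + (1 | participant_id) + (1 | sound_id),
    subj_only = response ~ size_k + (1 | participant_id))
  for (nm in names(forms)) {
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lmerTest::lmer(forms[[nm]], data = data, REML = FALSE, control = ctrl))),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5))
      return(.slope_report(fit, "size_k", nm))
    if (!is.null(fit) && nm == "subj_only")
      return(.slope_report(fit, "size_k", paste0(nm, " (singular)")))
  }
  fit <- stats::lm(response ~ size_k, data = data)
  .slope_report(fit, "size_k", "ols_fallback")
}

#' Linear mixed model linking memory benefit to cue-locked physiology
#'
#' Fits `benefit ~ 1 + modulation * size + (modulation | participant)` by
#' maximum likelihood, with the same stepwise simplification as
#' [fit_setsize_lmm()]. A constant modulation predictor is an error.
#'
#' @param data Data frame with columns `benefit`, `modulation`, `size_k`,
#'   `participant_id`.
#' @return List with `modulation`, `size`, and `interaction` slope reports
#'   (each as in [fit_setsize_lmm()]) plus the simplification `note`.
#' @export
fit_memory_physiology_lmm <- function(data) {
  if (!nrow(data)) stop("empty table: behavioural/EEG join produced no rows")
  if (stats::var(data$modulation) < 1e-12)
    stop("constant modulation predictor")
  data$size_k <- as.numeric(data$size_k)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  forms <- list(
    full = benefit ~ modulation * size_k + (modulation | participant_id),
    no_slope = benefit ~ modulation * size_k + (1 | participant_id))
  fit <- NULL; note <- NULL
  for (nm in names(forms)) {
    f <- tryCatch(suppressWarnings(suppressMessages(
      lmerTest::lmer(forms[[nm]], data = data, REML = FALSE, control = ctrl))),
      error = function(e) NULL)
    if (!is.null(f) && (!lme4::isSingular(f, tol = 1e-5) || nm == "no_slope")) {
      fit <- f; note <- nm; break
    }
  }
  if (is.null(fit)) {
    fit <- stats::lm(benefit ~ modulation * size_k, data = data)
    note <- "ols_fallback"
  }
  list(modulation = .slope_report(fit, "modulation", note),
       size = .slope_report(fit, "size_k", note),
       interaction = .slope_report(fit, "modulation:size_k", note),
       note = note)
}
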