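#' Run configuration
#'
#' Bundles every tunable of an end-to-end run: cohort size, generative model
#' parameters, cue-schedule variability, EEG synthesis/analysis settings,
#' and statistics settings. All randomness derives from the single `seed`
#' through a counter-based per-stage scheme, so identical configs give
#' identical outputs and stages can be rerun independently.
#'
#' @param seed Master integer seed.
#' @param n_participants Cohort size (default 31).
#' @param model,delta_px,forget_px,sigma_pre_px,p_guess,p_confuse_per_alt,incremental_subset
#'   Passed to [reactivation_model_params()].
#' @param n_passes_mean,n_passes_sd,n_passes_range Per-participant number of
#'   sleep cue passes: rounded Gaussian draw clamped to the range (the study
#'   delivered 11 +/- 1 (SEM) repetitions per sound, range 1-24).
#' @param n_subsamples,subsample_frac,screen_alpha Subsample robustness
#'   settings.
#' @param n_perm ICC permutation count.
#' @param eeg Logical: run the EEG arm.
#' @param eeg_fs EEG sampling rate, Hz.
#' @param eeg_passes Cue passes synthesized per participant in the EEG arm
#'   (the behavioural arm keeps its own schedule; EEG cost grows linearly).
#' @param evoked Parameters from [evoked_response_params()].
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A `run_config` (list).
#' @export
run_config <- function(seed = 1L, n_participants = 31L,
                       model = "PRH", delta_px = 8, forget_px = 5,
                       sigma_pre_px = 45, p_guess = 0.1,
                       p_confuse_per_alt = 0.07, incremental_subset = FALSE,
                       n_passes_mean = 11, n_passes_sd = 5.5,
                       n_passes_range = c(2, 24),
                       n_subsamples = 500L, subsample_frac = 0.5,
                       screen_alpha = 0.5, n_perm = 1e4L,
                       eeg = TRUE, eeg_fs = 512, eeg_passes = 2L,
                       evoked = evoked_response_params(),
                       out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `run_config` to validate.
#' @export
validate_config <- function(config) {
  if (is.null(config$n_participants) || config$n_participants < 1)
    stop("validation: n_participants must be at least 1")
  if (config$n_participants < 2)
    warning("within-subject statistics need at least 2 participants")
  if (is.null(config$seed)) stop("validation: seed must be explicit")
  if (config$eeg && config$eeg_fs < 128)
    stop("validation: eeg_fs must be at least 128 Hz")
  invisible(config)
}

#' Read / write a run configuration (JSON or YAML)
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @param config A `run_config`.
#' @return `read_run_config()` returns the `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- raw$evoked
  raw$evoked <- NULL
  cfg <- do.call(run_config, raw)
  if (!is.null(ev)) cfg$evoked <- do.call(evoked_response_params, ev)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$evoked <- unclass(out$evoked)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# counter-based per-stage seed derivation (stays inside 32-bit range)
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (k in idx) h <- (h * 48271 + as.numeric(k) * 9973 + 1) %% 2147483647
  as.integer(h) + 1L
}

#' Simulate a behavioural cohort
#'
#' For each participant: pre-sleep test, pre-sleep-based cued/non-cued
#' balancing, a randomized-blocks cue schedule with a participant-specific
#' number of passes (truncated mid-pass, so within a participant repetition
#' counts differ by at most one), training-exposure counts, and the
#' post-sleep test under the configured reactivation model.
#'
#' @param design A `tmr_design` (shared across the cohort; cueing
#'   assignments are per participant).
#' @param config A [run_config()].
#' @return List (`tmr_cohort`): `placements`, `cued_sets` (per participant),
#'   `cue_reps` (participant x sound repetition counts), `schedules` (list
#'   per participant), `familiarity`, `design`.
#' @export
simulate_cohort <- function(design, config = run_config()) {
  params <- reactivation_model_params(
    model = config$model, delta_px = config$delta_px,
    forget_px = config$forget_px, sigma_pre_px = config$sigma_pre_px,
    p_guess = config$p_guess, p_confuse_per_alt = config$p_confuse_per_alt,
    incremental_subset = config$incremental_subset)
  placements <- list(); cued_all <- list(); reps_all <- list()
  fam_all <- list(); schedules <- list()
  sets <- design$sets[!design$sets$practice, ]
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("p%02d", i)
    set.seed(derive_seed(config$seed, 1L, i))
    pre <- simulate_pre_sleep(design, params, participant_id = pid)
    scores <- score_presleep_sets(pre, design)
    scores <- merge(scores, sets[, c("set_id", "sound_id")], by = "set_id")
    bal <- balance_cuing(scores)
    n_passes <- round(stats::rnorm(1, config$n_passes_mean, config$n_passes_sd))
    n_passes <- max(config$n_passes_range[1],
                    min(config$n_passes_range[2], n_passes))
    cued_sounds <- bal[bal$cued, c("sound_id", "size_k")]
    n_sounds <- nrow(cued_sounds) + 1L
    trunc <- (n_passes - 1L) * n_sounds + sample.int(n_sounds, 1L)
    sched <- build_cue_sequence(cued_sounds, n_passes = n_passes,
                                novel_sound_id = design$novel_sound_id,
                                truncate_events = trunc)
    reps <- stats::aggregate(rep_idx ~ sound_id + size_k, data = sched, FUN = max)
    names(reps)[names(reps) == "rep_idx"] <- "n_reps"
    post <- simulate_post_sleep(pre, design, reps, params)
    fam <- simulate_training_exposure(design)
    placements[[i]] <- rbind(pre, post)
    cued_all[[i]] <- data.frame(participant_id = pid, bal[, c("set_id", "cued")])
    reps_all[[i]] <- data.frame(participant_id = pid, reps)
    fam_all[[i]] <- data.frame(participant_id = pid, fam$sets)
    schedules[[pid]] <- sched
  }
  structure(list(placements = do.call(rbind, placements),
                 cued_sets = do.call(rbind, cued_all),
                 cue_reps = do.call(rbind, reps_all),
                 familiarity = do.call(rbind, fam_all),
                 schedules = schedules, design = design),
            class = "tmr_cohort")
}

# drop participants with missing/NaN cells so the within-subject ANOVA is
# balanced (rare: a participant can lose every item of a cell to swap
# exclusion)
.complete_cells <- function(cells, dv) {
  bad <- unique(cells$participant_id[!is.finite(cells[[dv]])])
  if (length(bad)) {
    warning(length(bad), " participant(s) dropped from the '", dv,
            "' analysis due to empty cells")
    cells <- cells[!cells$participant_id %in% bad, ]
  }
  cells
}

# BIC Bayes factor for the cuing-by-size interaction on benefit cell means
.interaction_bf01 <- function(cells) {
  m0 <- stats::lm(benefit_px ~ participant_id + cued + factor(size_k), cells)
  m1 <- stats::lm(benefit_px ~ participant_id + cued * factor(size_k), cells)
  bic_bayes_factor(stats::BIC(m0), stats::BIC(m1))
}

#' Behavioural analysis of a simulated (or scored) cohort
#'
#' Runs the full behavioural statistics battery: swap-error and accuracy
#' ANOVAs, Tukey HSD on pre-sleep set-size differences, the benefit ANOVA
#' with the BIC Bayes factor for the interaction, the pre-sleep regression
#' adjustment, the lenient-criterion and cumulative per-set analyses, the
#' subsample robustness screen, ICC permutation tests (six- and two-item
#' sets), the six-item max-|z| outlier comparison, repetition-benefit
#' correlations, and the familiarity-covariate reanalysis.
#'
#' @param cohort A `tmr_cohort` from [simulate_cohort()].
#' @param config A [run_config()].
#' @return Nested list of results (`behavior_report`).
#' @export
analyze_behavior <- function(cohort, config = run_config()) {
  scored <- score_dataset(cohort$placements, cohort$design,
                          cued_sets = cohort$cued_sets)
  cells <- scored$summary
  cells <- .complete_cells(.complete_cells(cells, "benefit_px"), "pre_error_px")
  rep <- list()
  rep$anova_pre_error <- rm_anova(cells, "pre_error_px", c("cued", "size_k"))
  sz <- rep$anova_pre_error[rep$anova_pre_error$effect == "size_k", ]
  size_means <- tapply(cells$pre_error_px, cells$size_k, mean)
  rep$tukey_pre_size <- tukey_hsd(size_means, sz$ms_error, sz$df2,
                                  n = length(unique(cells$participant_id)) * 2)
  multi <- cells[cells$size_k > 1, ]
  rep$anova_pre_swap <- rm_anova(multi, "swap_pre", c("cued", "size_k"))
  rep$anova_swap_change <- rm_anova(multi, "swap_change", c("cued", "size_k"))
  rep$anova_benefit <- rm_anova(cells, "benefit_px", c("cued", "size_k"))
  rep$bf01_interaction <- .interaction_bf01(cells)
  rep$mean_benefit_cued <- mean(cells$benefit_px[cells$cued])
  rep$mean_benefit_noncued <- mean(cells$benefit_px[!cells$cued])
  adj <- cells
  adj$benefit_adj <- regress_out_presleep(adj$pre_error_px, adj$benefit_px)
  rep$anova_benefit_adjusted <- rm_anova(adj, "benefit_adj", c("cued", "size_k"))
  rep$anova_lenient <- rm_anova(cells, "lenient_change", c("cued", "size_k"))
  rep$pct_lenient_pre <- 100 * mean(scored$items$lenient_pre)
  setsum <- scored$set_summary
  cum <- stats::aggregate(cum_benefit_px ~ participant_id + size_k + cued,
                          data = setsum, FUN = mean)
  rep$anova_cumulative <- rm_anova(cum, "cum_benefit_px", c("cued", "size_k"))
  set.seed(derive_seed(config$seed, 2L, 1L))
  rep$subsample <- subsample_robustness(scored$items,
                                        n_datasets = config$n_subsamples,
                                        frac = config$subsample_frac,
                                        screen_alpha = config$screen_alpha)
  rep$icc <- list()
  for (k in c(6L, 2L)) {
    it <- scored$items[scored$items$size_k == k & !is.na(scored$items$benefit_px), ]
    it$uset <- paste(it$participant_id, it$set_id)
    set.seed(derive_seed(config$seed, 3L, k))
    rep$icc[[paste0("size", k)]] <- tryCatch(
      icc_with_permutation(it$benefit_px, it$uset, it$cued,
                           n_perm = config$n_perm, min_items = 2L),
      error = function(e) list(error = conditionMessage(e)))
  }
  it6 <- scored$items[scored$items$size_k == 6L &
                        !is.na(scored$items$benefit_px), ]
  it6$uset <- paste(it6$participant_id, it6$set_id)
  rep$max_abs_z <- tryCatch(
    suppressWarnings(max_abs_z_outlier(it6$benefit_px, it6$uset, it6$cued)),
    error = function(e) list(error = conditionMessage(e)))
  rep$repetition_correlations <- .rep_benefit_correlations(scored, cohort)
  fam_tab <- merge(stats::aggregate(benefit_px ~ participant_id + set_id +
                                      size_k + cued, data = scored$items,
                                    FUN = mean, na.action = stats::na.omit),
                   cohort$familiarity[, c("participant_id", "set_id", "familiarity")],
                   by = c("participant_id", "set_id"))
  names(fam_tab)[names(fam_tab) == "benefit_px"] <- "benefit"
  rep$familiarity <- familiarity_covariate_analysis(fam_tab)
  rep$scored <- scored
  structure(rep, class = "behavior_report")
}

# per-participant repetition vs cued-benefit correlations, by size class
.rep_benefit_correlations <- function(scored, cohort) {
  items <- scored$items
  out <- list()
  for (k in c(1L, 2L, 6L)) {
    it <- items[items$size_k == k & !is.na(items$cued) & items$cued, ]
    ben <- tapply(it$benefit_px, it$participant_id,
                  function(x) mean(x, na.rm = TRUE))
    rp <- cohort$cue_reps[cohort$cue_reps$size_k == k, ]
    reps <- tapply(rp$n_reps, rp$participant_id, mean)
    pids <- intersect(names(ben), names(reps))
    res <- tryCatch(
      repetition_benefit_correlation(as.numeric(ben[pids]),
                                     as.numeric(reps[pids])),
      error = function(e) list(error = conditionMessage(e)))
    if (k > 1L && is.null(res$error)) {
      res$prob_variant <- tryCatch(
        repetition_benefit_correlation(as.numeric(ben[pids]),
                                       as.numeric(reps[pids]),
                                       size_k = k, use_probability = TRUE),
        error = function(e) list(error = conditionMessage(e)))
    }
    out[[paste0("size", k)]] <- res
  }
  out
}

#' Simulate and analyse the EEG arm of a cohort
#'
#' Per participant, synthesizes a short NREM recording covering
#' `config$eeg_passes` passes of that participant's cue schedule, injects
#' the set-size-modulated evoked responses, and runs the full analysis:
#' cue-locked spectrograms, percent-change baseline correction, the
#' across-participant Bonferroni t-map with connected-component clusters,
#' per-trial cluster power, RMS spindle detection, spindle probability
#' timecourses, and the set-size linear mixed models. When a behaviour
#' report is supplied, the memory-physiology mixed model is fitted on
#' per-item benefits joined by participant and sound.
#'
#' @param cohort A `tmr_cohort`.
#' @param config A [run_config()].
#' @param behavior Optional `behavior_report` for the memory-physiology
#'   model.
#' @return List (`eeg_report`): `clusters`, `trials` (per-trial cluster
#'   powers and spindle measures), `lmm` (delta-theta, sigma, spindle
#'   probability, spindle amplitude), `memory_lmm` (or `NULL`).
#' @export
analyze_eeg_cohort <- function(cohort, config = run_config(), behavior = NULL) {
  fs <- config$eeg_fs
  pids <- names(cohort$schedules)
  trial_rows <- list(); corrected_means <- list(); tf_axes <- NULL
  corrected_by_pid <- list(); spind_by_pid <- list(); sched_by_pid <- list()
  for (i in seq_along(pids)) {
    pid <- pids[i]
    sched <- cohort$schedules[[pid]]
    n_sounds <- length(unique(sched$sound_id))
    sched <- sched[sched$pass <= config$eeg_passes, ]
    sched$onset_s <- sched$onset_s - sched$onset_s[1] + 2
    dur <- max(sched$onset_s) + 6
    set.seed(derive_seed(config$seed, 4L, i))
    bg <- synthesize_background(dur, fs = fs)
    inj <- inject_cue_responses(bg, sched, config$evoked)
    rec <- inj$recording
    tf <- epoch_and_spectrogram(rec, sched$onset_s)
    # participant-mean power first, then percent change: a single-trial
    # baseline is too noisy a denominator and biases the ratio upward
    pm <- apply(tf$power, c(2, 3), mean)
    corrected_means[[pid]] <- baseline_correct(pm, tf$times)
    bcols <- tf$times >= -0.5 & tf$times <= -0.2
    base_i <- rowMeans(pm[, bcols, drop = FALSE])
    corrected_by_pid[[pid]] <- baseline_correct(tf$power, tf$times,
                                                baseline = base_i)
    sched_by_pid[[pid]] <- sched[tf$kept, ]
    tf_axes <- list(times = tf$times, freqs = tf$freqs)
    spind_by_pid[[pid]] <- detect_spindles(rec$samples, fs)
  }
  arr <- array(NA_real_, c(length(pids), length(tf_axes$freqs),
                           length(tf_axes$times)))
  for (i in seq_along(pids)) arr[i, , ] <- corrected_means[[pids[i]]]
  clusters <- cluster_tmap(arr, tf_axes$times, tf_axes$freqs)
  pos <- Filter(function(cl) cl$sign > 0 &&
                  cl$time_range[2] > 0, clusters)
  pick <- function(pred) {
    cand <- Filter(pred, pos)
    if (!length(cand)) return(NULL)
    cand[[which.max(vapply(cand, function(cl) cl$n_points, 1))]]
  }
  cl_dt <- pick(function(cl) cl$freq_range[1] < 11 && cl$freq_range[2] <= 12)
  cl_sg <- pick(function(cl) cl$freq_range[1] >= 10 && cl$freq_range[2] > 11)
  for (i in seq_along(pids)) {
    pid <- pids[i]
    corr <- corrected_by_pid[[pid]]
    sch <- sched_by_pid[[pid]]
    n_tr <- dim(corr)[1]
    dtp <- sgp <- rep(NA_real_, n_tr)
    for (tr in seq_len(n_tr)) {
      if (!is.null(cl_dt)) dtp[tr] <- cluster_power(corr[tr, , ], cl_dt)
      if (!is.null(cl_sg)) sgp[tr] <- cluster_power(corr[tr, , ], cl_sg)
    }
    sp_win <- if (!is.null(cl_sg)) cl_sg$time_range else c(0.9, 1.45)
    spt <- spindle_probability_timecourse(spind_by_pid[[pid]], sch$onset_s,
                                          sch$size_k, cluster_window = sp_win)
    trial_rows[[pid]] <- data.frame(
      participant_id = pid, sound_id = sch$sound_id, size_k = sch$size_k,
      deltatheta_power = dtp, sigma_power = sgp,
      spindle_in_cluster = as.numeric(spt$trials$spindle_in_cluster),
      spindle_max_amp = spt$trials$max_amp_uv)
  }
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  fit_or_null <- function(col, subset = TRUE) {
    d <- trials[subset & !is.na(trials[[col]]), ]
    if (nrow(d) < 10) return(NULL)
    d$response <- d[[col]]
    fit_setsize_lmm(d)
  }
  lmm <- list(
    deltatheta = fit_or_null("deltatheta_power"),
    sigma = fit_or_null("sigma_power"),
    spindle_probability = fit_or_null("spindle_in_cluster"),
    spindle_amplitude = fit_or_null("spindle_max_amp"))
  memory_lmm <- NULL
  if (!is.null(behavior) && !is.null(cl_sg)) {
    mod <- stats::aggregate(sigma_power ~ participant_id + sound_id + size_k,
                            data = trials, FUN = mean)
    it <- behavior$scored$items[!is.na(behavior$scored$items$benefit_px), ]
    joined <- merge(it[, c("participant_id", "sound_id", "benefit_px")],
                    mod, by = c("participant_id", "sound_id"))
    if (nrow(joined)) {
      names(joined)[names(joined) == "benefit_px"] <- "benefit"
      names(joined)[names(joined) == "sigma_power"] <- "modulation"
      memory_lmm <- tryCatch(fit_memory_physiology_lmm(joined),
                             error = function(e) list(error = conditionMessage(e)))
    }
  }
  structure(list(clusters = clusters, delta_theta_cluster = cl_dt,
                 sigma_cluster = cl_sg, trials = trials, lmm = lmm,
                 memory_lmm = memory_lmm, axes = tf_axes),
            class = "eeg_report")
}

# strip heavy / non-serialisable members before writing the report JSON
.report_json <- function(rep) {
  slim <- rep
  slim$scored <- NULL
  if (!is.null(slim$subsample)) {
    slim$subsample$p_cuing <- NULL
    slim$subsample$p_interaction <- NULL
    slim$subsample <- unclass(slim$subsample)
  }
  for (nm in names(slim$icc)) slim$icc[[nm]] <- unclass(slim$icc[[nm]])
  if (!is.null(slim$max_abs_z$set_stats)) slim$max_abs_z$set_stats <- NULL
  slim
}

#' Run the full experiment pipeline
#'
#' design -> behavioural simulation -> scoring -> behavioural statistics ->
#' EEG simulation -> EEG analysis, all driven by one configuration. When
#' `config$out_dir` is set, writes the design CSVs, placements and scored
#' CSVs, a stats-report JSON, and a manifest recording package version,
#' seeds, and configuration. Identical configurations produce identical
#' reports.
#'
#' @param config A [run_config()].
#' @return List (`run_report`): `design`, `cohort`, `behavior`, `eeg`
#'   (`NULL` when disabled), `manifest`.
#' @export
run_experiment <- function(config = run_config()) {
  validate_config(config)
  stage <- "design"
  res <- tryCatch({
    design <- build_design(rng_seed = derive_seed(config$seed, 0L, 0L))
    stage <- "simulate_behavior"
    cohort <- simulate_cohort(design, config)
    stage <- "behavior_stats"
    behavior <- analyze_behavior(cohort, config)
    stage <- "eeg"
    eeg <- if (config$eeg) analyze_eeg_cohort(cohort, config, behavior) else NULL
    list(design = design, cohort = cohort, behavior = behavior, eeg = eeg)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(
    package = "napcue",
    version = as.character(utils::packageVersion("napcue")),
    seed = config$seed,
    stage_seeds = list(design = derive_seed(config$seed, 0L, 0L),
                       behavior = derive_seed(config$seed, 1L, 1L),
                       stats = derive_seed(config$seed, 2L, 1L),
                       eeg = derive_seed(config$seed, 4L, 1L)),
    config = unclass(config))
  manifest$config$evoked <- unclass(manifest$config$evoked)
  res$manifest <- manifest
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design_csv(res$design, config$out_dir)
    utils::write.csv(res$cohort$placements,
                     file.path(config$out_dir, "placements.csv"),
                     row.names = FALSE)
    utils::write.csv(res$behavior$scored$items,
                     file.path(config$out_dir, "scored_items.csv"),
                     row.names = FALSE)
    utils::write.csv(res$behavior$scored$summary,
                     file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(.report_json(res$behavior),
                         file.path(config$out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(res$eeg)) {
      utils::write.csv(res$eeg$trials,
                       file.path(config$out_dir, "eeg_trials.csv"),
                       row.names = FALSE)
      jsonlite::write_json(res$eeg$lmm,
                           file.path(config$out_dir, "eeg_lmm.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(res, class = "run_report")
}

#' Compare generative hypotheses by their diagnostic signatures
#'
#' For each model, simulates `n_cohorts` behavioural cohorts (sharing a
#' small pool of designs, regenerating behaviour each time) and records how
#' often each diagnostic fires: a significant cuing main effect, a
#' significant cuing-by-size interaction, a positive multi-item
#' repetition-benefit correlation, and a within-set agreement (ICC) deficit
#' for cued sets.
#'
#' @param config A [run_config()] (its `model` field is ignored).
#' @param models Character vector of model names.
#' @param n_cohorts Cohorts per model.
#' @param n_designs Designs in the shared pool.
#' @param alpha Significance level for the ANOVA diagnostics.
#' @return Data frame: one row per model with diagnostic rates in `[0, 1]`,
#'   including the joint parallel-reactivation pattern
#'   (`cuing_and_no_interaction`).
#' @export
compare_hypotheses <- function(config = run_config(), models = c("PRH",
                                                                 "LCH_divided",
                                                                 "LCH_random_subset",
                                                                 "LCH_biased_subset",
                                                                 "null"),
                               n_cohorts = 20L, n_designs = 4L,
                               alpha = 0.05) {
  stopifnot(length(models) >= 1, n_cohorts >= 1)
  n_designs <- min(n_designs, n_cohorts)
  designs <- lapply(seq_len(n_designs), function(d)
    build_design(rng_seed = derive_seed(config$seed, 10L, d)))
  rows <- list()
  for (m in models) {
    cue_sig <- int_sig <- rep_pos <- icc_lower <- logical(n_cohorts)
    for (cc in seq_len(n_cohorts)) {
      cfg <- config
      cfg$model <- m
      cfg$seed <- derive_seed(config$seed, 20L + match(m, models), cc)
      cfg$eeg <- FALSE
      design <- designs[[(cc - 1L) %% n_designs + 1L]]
      cohort <- simulate_cohort(design, cfg)
      scored <- score_dataset(cohort$placements, design,
                              cued_sets = cohort$cued_sets)
      cells <- suppressWarnings(.complete_cells(scored$summary, "benefit_px"))
      an <- rm_anova(cells, "benefit_px", c("cued", "size_k"))
      cue_sig[cc] <- an$p[an$effect == "cued"] < alpha
      int_sig[cc] <- an$p[an$effect == "cued:size_k"] < alpha
      it <- scored$items[scored$items$size_k > 1 & scored$items$cued %in% TRUE, ]
      ben <- tapply(it$benefit_px, it$participant_id,
                    function(x) mean(x, na.rm = TRUE))
      rp <- cohort$cue_reps[cohort$cue_reps$size_k > 0, ]
      reps <- tapply(rp$n_reps, rp$participant_id, mean)
      pids <- intersect(names(ben), names(reps))
      r <- tryCatch(repetition_benefit_correlation(as.numeric(ben[pids]),
                                                   as.numeric(reps[pids]))$r,
                    error = function(e) NA_real_)
      rep_pos[cc] <- !is.na(r) && r > 0
      it6 <- scored$items[scored$items$size_k == 6L &
                            !is.na(scored$items$benefit_px), ]
      it6$uset <- paste(it6$participant_id, it6$set_id)
      nsz <- stats::ave(it6$benefit_px, it6$uset, FUN = length)
      it6 <- it6[nsz >= 2, ]
      icc_lower[cc] <- tryCatch({
        mm <- function(cued_flag) {
          sel <- it6$cued == cued_flag
          .icc1(it6$benefit_px[sel], as.integer(factor(it6$uset[sel])))
        }
        mm(TRUE) < mm(FALSE)
      }, error = function(e) NA)
    }
    rows[[m]] <- data.frame(model = m,
                            cuing_effect = mean(cue_sig),
                            interaction = mean(int_sig),
                            cuing_and_no_interaction = mean(cue_sig & !int_sig),
                            repetition_correlation_positive = mean(rep_pos),
                            icc_cued_lower = mean(icc_lower, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
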