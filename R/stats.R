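#' Fully within-subject repeated-measures ANOVA (one or two factors)
#'
#' Classical sums-of-squares partitioning for a complete, balanced
#' within-subject design. Each effect is tested against its own
#' participant-by-effect interaction error term; no sphericity correction is
#' applied (tests report the uncorrected integer degrees of freedom).
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`. Effects whose
#' sum of squares is numerically zero are reported as `F = 0`, `p = 1`.
#'
#' @param data Data frame of cell values (typically cell means).
#' @param dv Name of the response column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the participant identifier column.
#' @return Data frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `pes` (partial eta squared), `ms_error` (the effect's error-term
#'   mean square, usable for Tukey HSD follow-ups).
#' @export
rm_anova <- function(data, dv, within, subject = "participant_id") {
  stopifnot(length(within) %in% 1:2)
  y <- data[[dv]]
  s <- factor(data[[subject]])
  A <- factor(data[[within[1]]])
  ns <- nlevels(s); na <- nlevels(A)
  two <- length(within) == 2L
  if (two) { B <- factor(data[[within[2]]]); nb <- nlevels(B) } else nb <- 1L
  if (nrow(data) != ns * na * nb || anyNA(y))
    stop("design must be complete and balanced with no missing cells")
  cnt <- if (two) table(s, A, B) else table(s, A)
  if (any(cnt != 1L)) stop("each participant must contribute every cell exactly once")

  g <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, A, mean)
  ss_s <- na * nb * sum((m_s - g)^2)
  ss_a <- ns * nb * sum((m_a - g)^2)
  m_as <- tapply(y, list(s, A), mean)
  ss_as <- nb * sum((sweep(sweep(m_as, 1, m_s), 2, m_a) + g)^2)
  out <- list()
  fstat <- function(ss_e, df_e, ss_err, df_err) {
    if (ss_e < 1e-12 * max(1, sum(y^2))) return(c(0, 1, 0, ss_err / df_err))
    Fv <- (ss_e / df_e) / (ss_err / df_err)
    c(Fv, stats::pf(Fv, df_e, df_err, lower.tail = FALSE),
      ss_e / (ss_e + ss_err), ss_err / df_err)
  }
  r <- fstat(ss_a, na - 1, ss_as, (na - 1) * (ns - 1))
  out[[1]] <- data.frame(effect = within[1], df1 = na - 1,
                         df2 = (na - 1) * (ns - 1),
                         F = r[1], p = r[2], pes = r[3], ms_error = r[4])
  if (two) {
    m_b <- tapply(y, B, mean)
    ss_b <- ns * na * sum((m_b - g)^2)
    m_bs <- tapply(y, list(s, B), mean)
    ss_bs <- na * sum((sweep(sweep(m_bs, 1, m_s), 2, m_b) + g)^2)
    m_ab <- tapply(y, list(A, B), mean)
    ss_ab <- ns * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
    ss_tot <- sum((y - g)^2)
    ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
    ss_abs <- max(ss_abs, 0)
    r <- fstat(ss_b, nb - 1, ss_bs, (nb - 1) * (ns - 1))
    out[[2]] <- data.frame(effect = within[2], df1 = nb - 1,
                           df2 = (nb - 1) * (ns - 1),
                           F = r[1], p = r[2], pes = r[3], ms_error = r[4])
    r <- fstat(ss_ab, (na - 1) * (nb - 1), ss_abs, (na - 1) * (nb - 1) * (ns - 1))
    out[[3]] <- data.frame(effect = paste(within, collapse = ":"),
                           df1 = (na - 1) * (nb - 1),
                           df2 = (na - 1) * (nb - 1) * (ns - 1),
                           F = r[1], p = r[2], pes = r[3], ms_error = r[4])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tukey HSD pairwise comparisons from an ANOVA error term
#'
#' Studentized-range test: `q = |m_i - m_j| / sqrt(MSE / n)` compared against
#' the studentized range distribution with `k` groups and `df_error` degrees
#' of freedom.
#'
#' @param means Named vector of level means.
#' @param ms_error Mean-square error from the ANOVA.
#' @param df_error Error degrees of freedom (> 0).
#' @param n Observations (participants) per level mean.
#' @return Data frame `level_1`, `level_2`, `diff`, `q`, `p`.
#' @export
tukey_hsd <- function(means, ms_error, df_error, n) {
  if (df_error <= 0) stop("df_error must be positive")
  k <- length(means)
  if (k < 2) stop("need at least two levels")
  nm <- names(means)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  dif <- means[pairs[1, ]] - means[pairs[2, ]]
  q <- abs(dif) / sqrt(ms_error / n)
  p <- stats::ptukey(q, k, df_error, lower.tail = FALSE)
  data.frame(level_1 = nm[pairs[1, ]], level_2 = nm[pairs[2, ]],
             diff = as.numeric(dif), q = as.numeric(q), p = as.numeric(p),
             row.names = NULL)
}

#' Bayes factor in favour of the null from two BIC values
#'
#' `BF01 = exp((BIC_alt - BIC_null) / 2)`, the standard BIC approximation to
#' the Bayes factor with equal prior odds.
#'
#' @param bic_null BIC of the null (restricted) model.
#' @param bic_alt BIC of the alternative model.
#' @return BF01 (evidence for the null; its reciprocal is BF10).
#' @export
bic_bayes_factor <- function(bic_null, bic_alt) {
  stopifnot(is.finite(bic_null), is.finite(bic_alt))
  exp((bic_alt - bic_null) / 2)
}

#' Regress pre-sleep error out of forgetting scores
#'
#' Fits the linear relation between pre-sleep error and forgetting, then
#' returns the residual plus the grand-mean forgetting, removing
#' set-dependent regression-to-the-mean while preserving the overall scale.
#'
#' @param pre_errors Numeric vector of pre-sleep errors.
#' @param forgetting Numeric vector of forgetting scores (same length).
#' @return Adjusted scores (same length); raw scores with a warning when the
#'   pre-sleep errors have no variance.
#' @export
regress_out_presleep <- function(pre_errors, forgetting) {
  stopifnot(length(pre_errors) == length(forgetting), length(forgetting) >= 3)
  if (stats::var(pre_errors) < 1e-12) {
    warning("pre-sleep errors have zero variance; returning raw scores")
    return(forgetting)
  }
  fit <- stats::lm(forgetting ~ pre_errors)
  as.numeric(stats::residuals(fit)) + mean(forgetting)
}

# adjusted Fisher-Pearson (bias-corrected) sample skewness
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  sqrt(n * (n - 1)) / (n - 2) * g1
}

#' Subsample robustness procedure for the cuing effect
#'
#' Repeatedly samples a fraction of items per participant and set size,
#' keeps only subsampled datasets whose pre-sleep set-size main effect is
#' negligible (`p >= screen_alpha`), and re-runs the benefit ANOVA on each
#' kept dataset. Reports how often the cuing effect and the cuing-by-size
#' interaction reach significance, the mean/median and skewness of both
#' p-value distributions, and the fraction of datasets in which cued sets
#' outperform non-cued sets.
#'
#' @param scored_items Per-item scored table (from [score_dataset()]`$items`)
#'   with a `cued` column.
#' @param n_datasets Number of screened datasets to accumulate.
#' @param frac Fraction of items sampled per participant x set size.
#' @param screen_alpha Pre-sleep screen: keep datasets with set-size
#'   `p >= screen_alpha`.
#' @param alpha Significance level for the reported rates.
#' @param rng_seed Optional integer seed.
#' @param max_attempts Attempt cap before aborting.
#' @return List (`subsample_report`): `n_kept`, `pct_cuing_significant`,
#'   `pct_interaction_significant`, `pct_cued_higher`, `mean_p_cuing`,
#'   `median_p_cuing`, `skew_p_cuing`, and the interaction analogues, plus
#'   the screen `acceptance_rate`.
#' @export
subsample_robustness <- function(scored_items, n_datasets = 500L, frac = 0.5,
                                 screen_alpha = 0.5, alpha = 0.05,
                                 rng_seed = NULL, max_attempts = 1e5L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(scored_items$cued)) stop("scored_items needs a 'cued' column")
  grp <- interaction(scored_items$participant_id, scored_items$size_k, drop = TRUE)
  idx_by_grp <- split(seq_len(nrow(scored_items)), grp)
  n_take <- vapply(idx_by_grp,
                   function(ix) max(1L, as.integer(round(frac * length(ix)))),
                   integer(1))
  p_cuing <- p_inter <- numeric(0)
  cued_higher <- logical(0)
  kept <- 0L; attempts <- 0L
  while (kept < n_datasets) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("subsample screen acceptance too low; aborting after ",
           max_attempts, " attempts (", kept, " kept)")
    take <- unlist(mapply(function(ix, n) ix[sample.int(length(ix), n)],
                          idx_by_grp, n_take, SIMPLIFY = FALSE))
    d <- scored_items[take, ]
    cells <- stats::aggregate(cbind(pre_error_px, benefit_px) ~
                                participant_id + size_k + cued, data = d,
                              FUN = function(x) mean(x, na.rm = TRUE),
                              na.action = stats::na.pass)
    if (anyNA(cells$pre_error_px) || anyNA(cells$benefit_px)) next
    n_cells <- length(unique(cells$size_k)) * 2 *
      length(unique(cells$participant_id))
    if (nrow(cells) != n_cells) next
    screen <- rm_anova(cells, "pre_error_px", c("cued", "size_k"))
    if (screen$p[screen$effect == "size_k"] < screen_alpha) next
    ben <- rm_anova(cells, "benefit_px", c("cued", "size_k"))
    kept <- kept + 1L
    p_cuing[kept] <- ben$p[ben$effect == "cued"]
    p_inter[kept] <- ben$p[ben$effect == "cued:size_k"]
    cued_higher[kept] <- mean(cells$benefit_px[cells$cued]) >
      mean(cells$benefit_px[!cells$cued])
  }
  structure(list(
    n_kept = kept, acceptance_rate = kept / attempts,
    pct_cuing_significant = 100 * mean(p_cuing < alpha),
    pct_interaction_significant = 100 * mean(p_inter < alpha),
    pct_cued_higher = 100 * mean(cued_higher),
    mean_p_cuing = mean(p_cuing), median_p_cuing = stats::median(p_cuing),
    skew_p_cuing = sample_skewness(p_cuing),
    mean_p_interaction = mean(p_inter),
    median_p_interaction = stats::median(p_inter),
    skew_p_interaction = sample_skewness(p_inter),
    p_cuing = p_cuing, p_interaction = p_inter), class = "subsample_report")
}

# one-way random-effects single-measure ICC, unbalanced groups allowed:
# values v, integer group index g (1..G), group sizes sz (all >= 2)
.icc1 <- function(v, g, sz = tabulate(g)) {
  G <- length(sz); N <- length(v)
  gm <- sum(v) / N
  s <- rowsum(v, g)
  ssb <- sum(s^2 / sz) - N * gm^2
  ssw <- sum(v^2) - sum(s^2 / sz)
  if (ssb + ssw < 1e-12) stop("degenerate data: zero total variance")
  msb <- ssb / (G - 1)
  msw <- ssw / (N - G)
  k0 <- (N - sum(sz^2) / N) / (G - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

# matrix convenience wrapper (columns = equal-size sets)
.icc1_matrix <- function(m) {
  g <- rep(seq_len(ncol(m)), each = nrow(m))
  .icc1(as.vector(m), g)
}

#' Within-set agreement (ICC) of item benefits with a permutation test
#'
#' Computes the one-way random-effects single-measure ICC of item benefits
#' grouped by set, separately for cued and non-cued sets, and tests the
#' difference `ICC_noncued - ICC_cued` against a permutation null built by
#' shuffling the item-to-set assignment separately within the cued and the
#' non-cued pools (group sizes are preserved by the shuffle). Because swap
#' exclusions leave sets with missing items, groups may be unbalanced: the
#' unbalanced one-way ANOVA estimator is used, and sets contributing fewer
#' than `min_items` benefits are dropped. The p-value uses the add-one
#' correction `(1 + #{|null| >= |observed|}) / (1 + n_perm)` and can
#' therefore never be zero.
#'
#' @param benefits Numeric vector of item benefits.
#' @param set_id Set identifier per benefit.
#' @param cued Logical per benefit.
#' @param n_perm Number of permutations.
#' @param min_items Minimum benefits per set for it to enter the analysis.
#' @param rng_seed Optional integer seed.
#' @return List (`icc_result`): `icc_cued`, `icc_noncued`, `diff`, `p_perm`,
#'   `n_perm`.
#' @export
icc_with_permutation <- function(benefits, set_id, cued, n_perm = 1e4L,
                                 min_items = 2L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  prep <- function(b, s) {
    sz <- table(s)
    keep <- s %in% names(sz)[sz >= min_items]
    b <- b[keep]; s <- s[keep]
    if (length(unique(s)) < 2L) stop("need at least 2 sets per condition")
    g <- as.integer(factor(s))
    list(v = b, g = g, sz = tabulate(g))
  }
  d_c <- prep(benefits[cued], set_id[cued])
  d_n <- prep(benefits[!cued], set_id[!cued])
  icc_c <- .icc1(d_c$v, d_c$g, d_c$sz)
  icc_n <- .icc1(d_n$v, d_n$g, d_n$sz)
  obs <- icc_n - icc_c
  nc <- length(d_c$v); nn <- length(d_n$v)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    d <- .icc1(d_n$v[sample.int(nn)], d_n$g, d_n$sz) -
      .icc1(d_c$v[sample.int(nc)], d_c$g, d_c$sz)
    if (abs(d) >= abs(obs)) exceed <- exceed + 1L
  }
  structure(list(icc_cued = icc_c, icc_noncued = icc_n, diff = obs,
                 p_perm = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm)), class = "icc_result")
}

#' Maximum absolute within-set z-score (outlier statistic)
#'
#' For each six-item set, item benefits are z-scored within the set (sample
#' SD) and the maximum absolute z is taken as the set's outlier statistic; a
#' set with zero within-set SD scores 0 with a warning. Cued and non-cued
#' sets are compared with an unpaired t-test. Sets left with fewer than
#' `min_items` benefits by swap exclusion are dropped.
#'
#' @param benefits Numeric vector of item benefits (up to six per set).
#' @param set_id Set identifier per benefit.
#' @param cued Logical per benefit (constant within set).
#' @param min_items Minimum benefits per set (at least 2 for a defined z).
#' @return List: `set_stats` (per-set statistic), `t`, `df`, `p`,
#'   `cohens_d`.
#' @export
max_abs_z_outlier <- function(benefits, set_id, cued, min_items = 2L) {
  sp <- split(data.frame(b = benefits, cued = cued), set_id)
  sp <- sp[vapply(sp, nrow, 1L) >= max(2L, min_items)]
  if (length(sp) < 4L) stop("too few sets with enough benefits")
  stat <- vapply(sp, function(d) {
    s <- stats::sd(d$b)
    if (s < 1e-12) { warning("zero within-set SD; statistic set to 0"); 0 }
    else max(abs((d$b - mean(d$b)) / s))
  }, numeric(1))
  is_cued <- vapply(sp, function(d) d$cued[1], logical(1))
  tt <- stats::t.test(stat[is_cued], stat[!is_cued], var.equal = TRUE)
  n1 <- sum(is_cued); n2 <- sum(!is_cued)
  sp_sd <- sqrt(((n1 - 1) * stats::var(stat[is_cued]) +
                   (n2 - 1) * stats::var(stat[!is_cued])) / (n1 + n2 - 2))
  d <- if (sp_sd > 0) (mean(stat[is_cued]) - mean(stat[!is_cued])) / sp_sd else 0
  list(set_stats = data.frame(set_id = names(stat), cued = is_cued,
                              max_abs_z = as.numeric(stat), row.names = NULL),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = d)
}

#' Correlation between cue repetitions and cuing benefit
#'
#' Pearson correlation (two-sided) of per-participant mean benefit against
#' per-participant mean cue repetitions; optionally against the at-least-once
#' reactivation probability `1 - ((k-1)/k)^n` instead of raw counts.
#'
#' @param benefit Numeric vector (one value per participant).
#' @param reps Numeric vector of mean repetitions, same length.
#' @param size_k If supplied together with `use_probability = TRUE`, the set
#'   size used to transform repetitions into reactivation probabilities.
#' @param use_probability Correlate against `reactivation_probability()`.
#' @return List: `r`, `p`, `n`.
#' @export
repetition_benefit_correlation <- function(benefit, reps, size_k = NULL,
                                           use_probability = FALSE) {
  stopifnot(length(benefit) == length(reps), length(benefit) >= 3)
  x <- if (use_probability) reactivation_probability(size_k, reps) else reps
  if (stats::var(x) < 1e-12 || stats::var(benefit) < 1e-12)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, benefit)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(benefit))
}

#' Set-level benefit analysis with a sound-familiarity covariate
#'
#' Linear model of set-level benefit on cuing status, set size, and their
#' interaction, with the training familiarity index as a covariate. Effects
#' are tested with Type II F-tests (each term against the model without it,
#' the interaction against the full model). A constant familiarity covariate
#' is dropped with a warning.
#'
#' @param set_table Data frame with columns `benefit`, `cued` (logical),
#'   `size_k`, `familiarity`.
#' @return Data frame `effect`, `df1`, `df2`, `F`, `p`.
#' @export
familiarity_covariate_analysis <- function(set_table) {
  st <- set_table
  st$size_k <- factor(st$size_k)
  has_fam <- stats::var(st$familiarity) > 1e-12
  if (!has_fam) warning("constant familiarity covariate dropped")
  base <- if (has_fam) "familiarity" else "1"
  f_test <- function(full, reduced) {
    a <- stats::anova(reduced, full)
    data.frame(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2], p = a$`Pr(>F)`[2])
  }
  m_full <- stats::lm(stats::reformulate(c(base, "cued*size_k"), "benefit"), st)
  m_main <- stats::lm(stats::reformulate(c(base, "cued", "size_k"), "benefit"), st)
  m_nocue <- stats::lm(stats::reformulate(c(base, "size_k"), "benefit"), st)
  m_nosize <- stats::lm(stats::reformulate(c(base, "cued"), "benefit"), st)
  rows <- rbind(cbind(effect = "cued", f_test(m_main, m_nocue)),
                cbind(effect = "size_k", f_test(m_main, m_nosize)),
                cbind(effect = "cued:size_k", f_test(m_full, m_main)))
  rows[, c("effect", "df1", "df2", "F", "p")]
}
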