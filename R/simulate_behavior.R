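#' Parameters of the generative reactivation models
#'
#' Encodes the competing hypotheses about what a sleep cue does to the items
#' of its set. `PRH` (parallel reactivation) gives every cued item the full
#' benefit `delta_px`; `LCH_divided` splits it evenly (`delta_px / k`);
#' `LCH_random_subset` samples one item of the set per cue presentation and
#' grants the full benefit to items sampled at least once (or, with
#' `incremental_subset = TRUE`, `delta_px * times_sampled / n_reps`);
#' `LCH_biased_subset` grants the full benefit to one fixed item per set;
#' `null` treats every item as non-cued. Non-cued fate is an error increase
#' of `forget_px` over sleep.
#'
#' Placements are the true location plus isotropic Gaussian noise
#' (`sigma_pre_px`), except that with probability `p_guess` a placement is a
#' uniform random guess on the grid disc, and with probability
#' `p_confuse_per_alt` per same-set alternative the item is placed at another
#' real same-set location (a genuine within-set memory confusion; this is
#' what makes swap rates grow with set size, as guesses alone cannot).
#' Guessing is largely an item property, not a trial property: an item whose
#' location was never consolidated is guessed at both tests. An item guessed
#' pre-sleep is guessed again post-sleep with probability `p_guess_keep`,
#' and an item known pre-sleep is newly guessed (forgotten entirely over
#' sleep) with probability `p_guess_new`, so the marginal post-sleep guess
#' rate stays close to `p_guess`.
#'
#' @param model Generative model name.
#' @param delta_px Cueing benefit in pixels of radial error reduction.
#' @param forget_px Error increase over sleep for non-benefiting items.
#' @param sigma_pre_px Isotropic placement noise scale, pixels.
#' @param p_guess Probability a pre-sleep placement is a uniform random
#'   guess.
#' @param p_guess_keep Probability an item guessed pre-sleep is guessed
#'   again post-sleep.
#' @param p_guess_new Probability an item known pre-sleep is guessed
#'   post-sleep (forgotten entirely over the nap); defaults to
#'   `0.3 * p_guess`, which keeps the marginal post-sleep guess rate close
#'   to the pre-sleep one.
#' @param p_confuse_per_alt Probability, per other real item in the set, of a
#'   within-set location confusion (drawn independently per phase).
#' @param n_reps_per_sound Nominal cue repetitions (used when no explicit cue
#'   schedule counts are supplied).
#' @param incremental_subset Random-subset variant: graded instead of
#'   all-or-nothing benefit.
#' @return A `reactivation_params` object (list).
#' @export
reactivation_model_params <- function(model = c("PRH", "LCH_divided",
                                                "LCH_random_subset",
                                                "LCH_biased_subset", "null"),
                                      delta_px = 8, forget_px = 5,
                                      sigma_pre_px = 45, p_guess = 0.1,
                                      p_guess_keep = 0.8, p_guess_new = NULL,
                                      p_confuse_per_alt = 0.07,
                                      n_reps_per_sound = 11L,
                                      incremental_subset = FALSE) {
  model <- match.arg(model)
  if (is.null(p_guess_new)) p_guess_new <- 0.3 * p_guess
  stopifnot(delta_px >= 0, forget_px >= 0, sigma_pre_px >= 0,
            p_guess >= 0, p_guess <= 1, p_guess_keep >= 0, p_guess_keep <= 1,
            p_guess_new >= 0, p_guess_new <= 1, p_confuse_per_alt >= 0,
            n_reps_per_sound >= 0)
  structure(list(model = model, delta_px = delta_px, forget_px = forget_px,
                 sigma_pre_px = sigma_pre_px, p_guess = p_guess,
                 p_guess_keep = p_guess_keep, p_guess_new = p_guess_new,
                 p_confuse_per_alt = p_confuse_per_alt,
                 n_reps_per_sound = as.integer(n_reps_per_sound),
                 incremental_subset = incremental_subset),
            class = "reactivation_params")
}

#' Probability of at-least-once reactivation under one-item-per-cue sampling
#'
#' If each cue presentation reactivates exactly one item sampled uniformly
#' from a set of `size_k` items, the probability that a given item is
#' reactivated at least once over `n` presentations is
#' `1 - ((size_k - 1) / size_k)^n`.
#'
#' @param size_k Set size (>= 1); vectorised.
#' @param n Number of cue repetitions (>= 0); vectorised.
#' @return Probability in `[0, 1)`.
#' @export
reactivation_probability <- function(size_k, n) {
  if (any(size_k < 1)) stop("size_k must be >= 1")
  if (any(n < 0)) stop("n must be >= 0")
  1 - ((size_k - 1) / size_k)^n
}

# uniform points on the grid disc
.sample_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# rescale points that fell outside the disc back onto the rim
.clip_disc <- function(xy, radius) {
  rr <- sqrt(rowSums(xy^2))
  out <- rr > radius
  if (any(out)) xy[out, ] <- xy[out, , drop = FALSE] * (radius / rr[out])
  xy
}

# one phase of placements for every item of a design, with the guess flags
# decided by the caller (guessing is persistent across phases)
.place_items <- function(items, params, grid, guess) {
  n <- nrow(items)
  xy <- cbind(items$x, items$y) +
    matrix(stats::rnorm(2 * n, 0, params$sigma_pre_px), n, 2)
  # within-set confusions: place at another real same-set item's location
  p_conf <- params$p_confuse_per_alt * (items$size_k - 1L)
  conf <- stats::runif(n) < p_conf
  if (any(conf)) {
    for (i in which(conf)) {
      alt <- which(items$set_id == items$set_id[i] &
                     items$item_id != items$item_id[i])
      j <- if (length(alt) == 1L) alt else sample(alt, 1L)
      xy[i, ] <- c(items$x[j], items$y[j]) + stats::rnorm(2, 0, params$sigma_pre_px)
    }
  }
  if (any(guess)) xy[guess, ] <- .sample_disc(sum(guess), grid$radius_px)
  .clip_disc(xy, grid$radius_px)
}

#' Simulate the pre-sleep placement test
#'
#' @param design A `tmr_design` from [build_design()].
#' @param params A [reactivation_model_params()].
#' @param rng_seed Optional integer seed.
#' @param participant_id Identifier stamped on the records.
#' @return Data frame of placement records: `participant_id`, `item_id`,
#'   `phase` (`"pre"`), `x`, `y`.
#' @export
simulate_pre_sleep <- function(design, params = reactivation_model_params(),
                               rng_seed = NULL, participant_id = "p01") {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  items <- design$items
  guess <- stats::runif(nrow(items)) < params$p_guess
  xy <- .place_items(items, params, design$grid, guess)
  out <- data.frame(participant_id = participant_id, item_id = items$item_id,
                    phase = "pre", x = xy[, 1], y = xy[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "guess") <- guess
  out
}

# per-item benefit (px of error reduction; negative = forgetting) by model
.item_benefits <- function(items, cue_counts, params) {
  n <- nrow(items)
  counts <- cue_counts$n_reps[match(items$sound_id, cue_counts$sound_id)]
  counts[is.na(counts)] <- 0L
  b <- rep(-params$forget_px, n)
  if (params$model == "null") return(b)
  cued <- counts > 0L
  if (params$model == "PRH") {
    b[cued] <- params$delta_px
  } else if (params$model == "LCH_divided") {
    b[cued] <- params$delta_px / items$size_k[cued]
  } else if (params$model == "LCH_biased_subset") {
    for (s in unique(items$set_id[cued])) {
      idx <- which(items$set_id == s)
      lucky <- if (length(idx) == 1L) idx else sample(idx, 1L)
      b[lucky] <- params$delta_px
    }
  } else if (params$model == "LCH_random_subset") {
    for (s in unique(items$set_id[cued])) {
      idx <- which(items$set_id == s)
      n_reps <- counts[idx[1]]
      draws <- if (length(idx) == 1L) rep(idx, n_reps) else
        sample(idx, n_reps, replace = TRUE)
      times <- tabulate(match(draws, idx), length(idx))
      if (params$incremental_subset) {
        got <- times > 0L
        b[idx[got]] <- params$delta_px * times[got] / n_reps
      } else {
        b[idx[times > 0L]] <- params$delta_px
      }
    }
  }
  b
}

#' Simulate the post-sleep placement test
#'
#' Each item's pre-sleep radial error is shifted by the model-specific
#' benefit (floored at zero) and the placement direction is re-randomised.
#' The confusion process is drawn afresh, while guessing persists from the
#' pre test (`p_guess_keep` / `p_guess_new`; see
#' [reactivation_model_params()]).
#'
#' @param pre_records Pre-sleep placements from [simulate_pre_sleep()].
#' @param design A `tmr_design`.
#' @param cue_counts Data frame `sound_id`, `n_reps` giving how often each
#'   sound was presented during sleep (0 or absent = not cued).
#' @param params A [reactivation_model_params()].
#' @param rng_seed Optional integer seed.
#' @return Data frame of placement records with `phase = "post"`.
#' @export
simulate_post_sleep <- function(pre_records, design, cue_counts,
                                params = reactivation_model_params(),
                                rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  items <- design$items
  pre <- pre_records[match(items$item_id, pre_records$item_id), ]
  r_pre <- sqrt((pre$x - items$x)^2 + (pre$y - items$y)^2)
  b <- .item_benefits(items, cue_counts, params)
  r_post <- pmax(0, r_pre - b)
  n <- nrow(items)
  th <- stats::runif(n, 0, 2 * pi)
  xy <- cbind(items$x + r_post * cos(th), items$y + r_post * sin(th))
  # keep the intended radial error where some direction stays on the grid
  radius <- design$grid$radius_px
  out <- sqrt(rowSums(xy^2)) > radius
  for (i in which(out)) {
    for (tr in 1:20) {
      a <- stats::runif(1, 0, 2 * pi)
      cand <- c(items$x[i] + r_post[i] * cos(a), items$y[i] + r_post[i] * sin(a))
      if (sqrt(sum(cand^2)) <= radius) { xy[i, ] <- cand; out[i] <- FALSE; break }
    }
  }
  xy <- .clip_disc(xy, radius)
  # fresh confusion process; guessing persists from the pre test
  p_conf <- params$p_confuse_per_alt * (items$size_k - 1L)
  conf <- stats::runif(n) < p_conf
  for (i in which(conf)) {
    alt <- which(items$set_id == items$set_id[i] & items$item_id != items$item_id[i])
    j <- if (length(alt) == 1L) alt else sample(alt, 1L)
    xy[i, ] <- .clip_disc(matrix(c(items$x[j], items$y[j]) +
                                   stats::rnorm(2, 0, params$sigma_pre_px), 1, 2),
                          radius)
  }
  pre_guess <- attr(pre_records, "guess")
  if (is.null(pre_guess)) pre_guess <- stats::runif(n) < params$p_guess
  guess <- ifelse(pre_guess, stats::runif(n) < params$p_guess_keep,
                  stats::runif(n) < params$p_guess_new)
  if (any(guess)) xy[guess, ] <- .sample_disc(sum(guess), radius)
  data.frame(participant_id = pre$participant_id, item_id = items$item_id,
             phase = "post", x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Simulate training exposure (trials to criterion and sound familiarity)
#'
#' Trials-to-criterion per item are `2 + Poisson(1.63)` (mean 3.63, matching
#' the feedback-training criterion of two consecutive correct placements,
#' which needs at least two trials). Each positioning trial plays the set
#' sound about three times (trial start, pick-up, drop) and each exposure
#' trial plays it twice, so a set's familiarity index is
#' `sum over its items of (3 * trials + 2)`.
#'
#' @param design A `tmr_design`.
#' @param rng_seed Optional integer seed.
#' @param deterministic If `TRUE`, every item takes exactly 3 trials.
#' @return List with `items` (`item_id`, `trials`) and `sets` (`set_id`,
#'   `sound_id`, `size_k`, `familiarity`).
#' @export
simulate_training_exposure <- function(design, rng_seed = NULL,
                                       deterministic = FALSE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  items <- design$items
  trials <- if (deterministic) rep(3L, nrow(items)) else
    2L + stats::rpois(nrow(items), 1.63)
  plays <- 3L * trials + 2L
  fam <- tapply(plays, items$set_id, sum)
  sets <- design$sets
  sets$familiarity <- as.numeric(fam[sets$set_id])
  list(items = data.frame(item_id = items$item_id, trials = trials,
                          stringsAsFactors = FALSE),
       sets = sets[, c("set_id", "sound_id", "size_k", "familiarity")])
}
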