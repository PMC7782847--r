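#' Scoring configuration
#'
#' @param correct_criterion_px Lenient correctness criterion: a placement is
#'   counted correct if its accuracy error is strictly below this distance
#'   (100 px corresponds to 27.7 mm at the study's display scale).
#' @param n_candidates Candidate locations per set used for swap
#'   classification (six for every set size, real plus phantom).
#' @return A `scoring_config` object (list).
#' @export
scoring_config <- function(correct_criterion_px = 100, n_candidates = 6L) {
  stopifnot(correct_criterion_px > 0)
  structure(list(correct_criterion_px = correct_criterion_px,
                 n_candidates = as.integer(n_candidates)),
            class = "scoring_config")
}

#' Classify a placement as a swap error
#'
#' A placement is swapped if it lies strictly closer to one of the set's
#' other candidate locations (real or phantom) than to the item's own true
#' location. Because every set carries six candidates regardless of its real
#' size, large guessing errors are flagged at the same rate in all set sizes.
#' Exact ties are not swaps.
#'
#' @param placed Length-2 numeric (x, y) placement.
#' @param true_location Length-2 numeric, the item's correct location.
#' @param candidate_locations 6 x 2 matrix of the set's candidate locations
#'   (must include `true_location`).
#' @return Logical flag.
#' @export
classify_swap <- function(placed, true_location, candidate_locations) {
  candidate_locations <- as.matrix(candidate_locations)
  if (nrow(candidate_locations) != 6L)
    stop("exactly 6 candidate locations are required")
  d <- sqrt((candidate_locations[, 1] - placed[1])^2 +
              (candidate_locations[, 2] - placed[2])^2)
  d_true <- sqrt(sum((true_location - placed)^2))
  is_true <- abs(candidate_locations[, 1] - true_location[1]) < 1e-9 &
    abs(candidate_locations[, 2] - true_location[2]) < 1e-9
  if (!any(is_true)) stop("true_location is not among candidate_locations")
  any(d[!is_true] < d_true)
}

#' Euclidean accuracy error in pixels
#'
#' @param placed n x 2 matrix (or length-2 vector) of placements.
#' @param true_location n x 2 matrix (or length-2 vector) of true locations.
#' @return Numeric vector of distances.
#' @export
accuracy_error <- function(placed, true_location) {
  placed <- rbind(placed); true_location <- rbind(true_location)
  unname(sqrt((placed[, 1] - true_location[, 1])^2 +
                (placed[, 2] - true_location[, 2])^2))
}

# vectorised swap flags for a placement table joined to design items;
# candidates come six-per-set in set order, so a 6-row reshape indexes them
.swap_flags <- function(px, py, items, candidates) {
  set_order <- candidates$set_id[seq(1, nrow(candidates), by = 6)]
  cx <- matrix(candidates$x, nrow = 6)
  cy <- matrix(candidates$y, nrow = 6)
  col <- match(items$set_id, set_order)
  cand_x <- t(cx[, col, drop = FALSE])
  cand_y <- t(cy[, col, drop = FALSE])
  d2 <- (cand_x - px)^2 + (cand_y - py)^2
  d2_true <- (items$x - px)^2 + (items$y - py)^2
  own <- abs(cand_x - items$x) < 1e-9 & abs(cand_y - items$y) < 1e-9
  d2[own] <- Inf
  matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))
  matrixStats_rowMins(d2) < d2_true
}

#' Score a pre/post placement dataset
#'
#' Computes per item and phase: swap flag (six-candidate rule), accuracy
#' error (reported only for unswapped placements), lenient correctness
#' (error strictly below the criterion), and the sleep benefit
#' `pre_error - post_error` (positive = improvement), computed only for
#' items unswapped in both phases. Items missing a phase are dropped with a
#' warning. Practice items are excluded.
#'
#' @param placements Long data frame: `participant_id`, `item_id`, `phase`
#'   (`"pre"`/`"post"`), `x`, `y`.
#' @param design A `tmr_design`.
#' @param config A [scoring_config()].
#' @param cued_sets Optional data frame `set_id`, `cued` (plus, when cueing
#'   assignments differ across participants, a `participant_id` column); if
#'   supplied, a `cued` column and cued-by-size summaries are produced.
#' @return List with `items` (one row per participant x item), `summary`
#'   (participant x set size x cued cell means), and `set_summary` (per-set
#'   cumulative and mean benefits).
#' @export
score_dataset <- function(placements, design, config = scoring_config(),
                          cued_sets = NULL) {
  items <- design$items[!design$items$practice, ]
  pl <- placements[placements$item_id %in% items$item_id, ]
  wide <- merge(
    pl[pl$phase == "pre", c("participant_id", "item_id", "x", "y")],
    pl[pl$phase == "post", c("participant_id", "item_id", "x", "y")],
    by = c("participant_id", "item_id"), suffixes = c("_pre", "_post"),
    all = TRUE)
  miss <- is.na(wide$x_pre) | is.na(wide$x_post)
  if (any(miss)) {
    warning(sum(miss), " item(s) missing a phase were dropped")
    wide <- wide[!miss, ]
  }
  it <- items[match(wide$item_id, items$item_id), ]
  pre_err_raw <- accuracy_error(cbind(wide$x_pre, wide$y_pre), cbind(it$x, it$y))
  post_err_raw <- accuracy_error(cbind(wide$x_post, wide$y_post), cbind(it$x, it$y))
  swap_pre <- .swap_flags(wide$x_pre, wide$y_pre, it, design$candidates)
  swap_post <- .swap_flags(wide$x_post, wide$y_post, it, design$candidates)
  crit <- config$correct_criterion_px
  scored <- data.frame(
    participant_id = wide$participant_id, item_id = wide$item_id,
    set_id = it$set_id, size_k = it$size_k, sound_id = it$sound_id,
    swap_pre = swap_pre, swap_post = swap_post,
    pre_error_px = ifelse(swap_pre, NA_real_, pre_err_raw),
    post_error_px = ifelse(swap_post, NA_real_, post_err_raw),
    lenient_pre = pre_err_raw < crit,
    lenient_post = post_err_raw < crit,
    stringsAsFactors = FALSE)
  scored$benefit_px <- ifelse(!swap_pre & !swap_post,
                              pre_err_raw - post_err_raw, NA_real_)
  if (!is.null(cued_sets)) {
    if ("participant_id" %in% names(cued_sets)) {
      key <- paste(scored$participant_id, scored$set_id)
      ckey <- paste(cued_sets$participant_id, cued_sets$set_id)
      scored$cued <- cued_sets$cued[match(key, ckey)]
    } else {
      scored$cued <- cued_sets$cued[match(scored$set_id, cued_sets$set_id)]
    }
  }

  group_cols <- c("participant_id", "size_k", if (!is.null(cued_sets)) "cued")
  g <- interaction(scored[group_cols], drop = TRUE)
  agg <- function(x, f) as.numeric(tapply(x, g, f))
  key <- do.call(rbind, strsplit(levels(g), ".", fixed = TRUE))
  summary <- data.frame(participant_id = key[, 1],
                        size_k = as.integer(key[, 2]),
                        stringsAsFactors = FALSE)
  if (!is.null(cued_sets)) summary$cued <- as.logical(key[, 3])
  summary$n_items <- as.integer(table(g))
  summary$swap_pre <- agg(scored$swap_pre, mean)
  summary$swap_post <- agg(scored$swap_post, mean)
  summary$swap_change <- summary$swap_post - summary$swap_pre
  summary$pre_error_px <- agg(scored$pre_error_px, function(x) mean(x, na.rm = TRUE))
  summary$post_error_px <- agg(scored$post_error_px, function(x) mean(x, na.rm = TRUE))
  summary$benefit_px <- agg(scored$benefit_px, function(x) mean(x, na.rm = TRUE))
  summary$lenient_pre <- agg(scored$lenient_pre, mean)
  summary$lenient_post <- agg(scored$lenient_post, mean)
  summary$lenient_change <- summary$lenient_post - summary$lenient_pre

  gs <- interaction(scored$participant_id, scored$set_id, drop = TRUE)
  ks <- do.call(rbind, strsplit(levels(gs), ".", fixed = TRUE))
  set_summary <- data.frame(
    participant_id = ks[, 1], set_id = ks[, 2],
    size_k = as.integer(tapply(scored$size_k, gs, function(x) x[1])),
    n_benefit = as.integer(tapply(scored$benefit_px, gs,
                                  function(x) sum(!is.na(x)))),
    cum_benefit_px = as.numeric(tapply(scored$benefit_px, gs,
                                       function(x) sum(x, na.rm = TRUE))),
    mean_benefit_px = as.numeric(tapply(scored$benefit_px, gs,
                                        function(x) mean(x, na.rm = TRUE))),
    stringsAsFactors = FALSE)
  if (!is.null(cued_sets)) {
    if ("participant_id" %in% names(cued_sets)) {
      key <- paste(set_summary$participant_id, set_summary$set_id)
      ckey <- paste(cued_sets$participant_id, cued_sets$set_id)
      set_summary$cued <- cued_sets$cued[match(key, ckey)]
    } else {
      set_summary$cued <- cued_sets$cued[match(set_summary$set_id, cued_sets$set_id)]
    }
  }
  list(items = scored, summary = summary, set_summary = set_summary)
}

#' Pre-sleep per-set scores used for cued/non-cued balancing
#'
#' @param pre_placements Pre-sleep placement records.
#' @param design A `tmr_design`.
#' @param config A [scoring_config()].
#' @return Data frame `set_id`, `size_k`, `n_incorrect` (placements at or
#'   beyond the correctness criterion, or swapped), `n_swap`, `sum_abs_err`
#'   (summed accuracy error over unswapped placements); practice sets
#'   excluded.
#' @export
score_presleep_sets <- function(pre_placements, design,
                                config = scoring_config()) {
  items <- design$items[!design$items$practice, ]
  pl <- pre_placements[match(items$item_id, pre_placements$item_id), ]
  err <- accuracy_error(cbind(pl$x, pl$y), cbind(items$x, items$y))
  swap <- .swap_flags(pl$x, pl$y, items, design$candidates)
  incorrect <- swap | err >= config$correct_criterion_px
  acc <- ifelse(swap, 0, err)
  data.frame(set_id = sort(unique(items$set_id)),
             size_k = as.integer(tapply(items$size_k, items$set_id, `[`, 1)),
             n_incorrect = as.integer(tapply(incorrect, items$set_id, sum)),
             n_swap = as.integer(tapply(swap, items$set_id, sum)),
             sum_abs_err = as.numeric(tapply(acc, items$set_id, sum)),
             stringsAsFactors = FALSE)
}
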