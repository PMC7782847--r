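#' Grid specification for the circular placement arena
#'
#' The study arena is a disc on which object images are placed. Distance
#' constraints keep item locations away from the centre and border, keep all
#' true item locations mutually distinguishable, and keep the six candidate
#' locations of a set far enough apart that misplacing an item near another
#' candidate can be classified as a swap rather than a graded accuracy error.
#'
#' @param radius_px Grid radius in pixels.
#' @param px_to_mm Millimetres per pixel (image tiles are 125 px = 34.6 mm).
#' @param min_center_dist Minimum distance of any location from the grid
#'   centre, pixels.
#' @param min_border_dist Minimum distance of any location from the grid
#'   border, pixels.
#' @param min_pairwise_dist Minimum distance between true item locations of
#'   different sets, pixels.
#' @param min_within_set_dist Minimum distance between the six candidate
#'   locations of one set, pixels.
#' @return A `grid_spec` object (list).
#' @export
grid_spec <- function(radius_px = 540, px_to_mm = 34.6 / 125,
                      min_center_dist = 50, min_border_dist = 50,
                      min_pairwise_dist = 41, min_within_set_dist = 400) {
  if (radius_px <= min_center_dist + min_border_dist)
    stop("radius_px must exceed min_center_dist + min_border_dist")
  if (min_within_set_dist <= min_pairwise_dist)
    stop("min_within_set_dist must exceed min_pairwise_dist")
  structure(list(radius_px = radius_px, px_to_mm = px_to_mm,
                 min_center_dist = min_center_dist,
                 min_border_dist = min_border_dist,
                 min_pairwise_dist = min_pairwise_dist,
                 min_within_set_dist = min_within_set_dist),
            class = "grid_spec")
}

# uniform draws in the annulus allowed by centre/border rules
.sample_annulus <- function(n, grid) {
  rmin <- grid$min_center_dist
  rmax <- grid$radius_px - grid$min_border_dist
  r <- sqrt(stats::runif(n, rmin^2, rmax^2))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Sample one set's six candidate locations
#'
#' Rejection sampling of six points that are inside the allowed annulus,
#' pairwise at least `min_within_set_dist` apart, and at least
#' `min_pairwise_dist` from every point in `existing` (the true item
#' locations already placed for other sets). Each attempt draws a batch of
#' annulus points, discards those too close to `existing`, and then tries
#' several greedy orderings to extract six mutually distant points.
#'
#' @param grid A [grid_spec()].
#' @param existing Numeric matrix (n x 2) of already-placed points the new
#'   candidates must avoid; may have zero rows.
#' @param rng_seed Optional integer seed; `NULL` uses the current RNG state.
#' @param batch Proposals drawn per attempt.
#' @param n_orders Greedy extraction orders tried per proposal batch.
#' @param retry_cap Maximum attempts before declaring the layout infeasible.
#' @return A 6 x 2 matrix of (x, y) coordinates, origin at the grid centre.
#' @export
sample_set_locations <- function(grid = grid_spec(), existing = NULL,
                                 rng_seed = NULL, batch = 400L,
                                 n_orders = 12L, retry_cap = 1e5L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(existing)) existing <- matrix(numeric(0), 0, 2)
  existing <- as.matrix(existing)
  d2min <- grid$min_pairwise_dist^2
  w2min <- grid$min_within_set_dist^2
  nt <- nrow(existing)
  tx <- existing[, 1]; ty <- existing[, 2]
  for (attempt in seq_len(retry_cap)) {
    p <- .sample_annulus(batch, grid)
    px <- p[, 1]; py <- p[, 2]
    if (nt > 0) {
      dx <- outer(px, tx, "-"); dy <- outer(py, ty, "-")
      keep <- rowSums(dx * dx + dy * dy < d2min) == 0
      px <- px[keep]; py <- py[keep]
    }
    m <- length(px)
    if (m < 6) next
    for (ord in seq_len(n_orders)) {
      o <- sample.int(m)
      ox <- px[o]; oy <- py[o]
      selx <- ox[1]; sely <- oy[1]; k <- 1L
      for (i in 2:m) {
        if (all((selx - ox[i])^2 + (sely - oy[i])^2 >= w2min)) {
          k <- k + 1L
          selx <- c(selx, ox[i]); sely <- c(sely, oy[i])
          if (k == 6L)
            return(cbind(x = selx, y = sely))
        }
      }
    }
  }
  stop("layout infeasible: could not place 6 candidate locations ",
       "within the retry cap (over-constrained grid)")
}

# random partition of multi-item sets into two- and six-item conditions
.partition_multi <- function(multi_ids, n_six = 6L) {
  six <- sample(multi_ids, n_six)
  list(six = six, two = setdiff(multi_ids, six))
}

#' Build the full experimental design
#'
#' Creates the set structure (24 multi-item sets randomly partitioned into 18
#' two-item and 6 six-item sets, 18 usable one-item sets, 3 one-item practice
#' sets, one novel sound), samples six candidate grid locations per set, picks
#' each set's true item locations as a random subset of its candidates, and
#' schedules the 90 scored items into six learning blocks.
#'
#' @param grid A [grid_spec()].
#' @param n_multi Number of multi-item sets to partition.
#' @param n_six Number of multi-item sets that become six-item sets.
#' @param n_single Number of usable one-item sets.
#' @param n_practice Number of practice one-item sets (excluded from scoring).
#' @param rng_seed Integer seed.
#' @return A list of class `tmr_design` with elements `sets` (one row per
#'   set: `set_id`, `size_k`, `sound_id`, `practice`), `items` (one row per
#'   item: `item_id`, `set_id`, `size_k`, `sound_id`, `practice`, `block`,
#'   `x`, `y`, `cand_idx`), `candidates` (six rows per set: `set_id`,
#'   `cand_idx`, `x`, `y`, `is_true`), `novel_sound_id`, and `grid`.
#' @export
build_design <- function(grid = grid_spec(), n_multi = 24L, n_six = 6L,
                         n_single = 18L, n_practice = 3L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  multi_ids <- sprintf("M%02d", seq_len(n_multi))
  part <- .partition_multi(multi_ids, n_six)
  single_ids <- sprintf("S%02d", seq_len(n_single))
  practice_ids <- if (n_practice > 0) sprintf("P%02d", seq_len(n_practice)) else character(0)
  sets <- data.frame(
    set_id = c(part$six, part$two, single_ids, practice_ids),
    size_k = c(rep(6L, length(part$six)), rep(2L, length(part$two)),
               rep(1L, n_single), rep(1L, n_practice)),
    practice = c(rep(FALSE, n_multi + n_single), rep(TRUE, n_practice)),
    stringsAsFactors = FALSE)
  sets$sound_id <- paste0("snd_", sets$set_id)

  # sample layouts set by set; the 41-px rule applies to true item locations
  order_idx <- sample.int(nrow(sets))
  true_pts <- matrix(numeric(0), 0, 2)
  cand_list <- vector("list", nrow(sets))
  true_idx_list <- vector("list", nrow(sets))
  for (i in order_idx) {
    pts <- sample_set_locations(grid, existing = true_pts)
    k <- sets$size_k[i]
    t_idx <- sample.int(6L, k)
    cand_list[[i]] <- pts
    true_idx_list[[i]] <- t_idx
    true_pts <- rbind(true_pts, pts[t_idx, , drop = FALSE])
  }

  candidates <- do.call(rbind, lapply(seq_len(nrow(sets)), function(i) {
    data.frame(set_id = sets$set_id[i], cand_idx = 1:6,
               x = cand_list[[i]][, 1], y = cand_list[[i]][, 2],
               is_true = seq_len(6) %in% true_idx_list[[i]],
               stringsAsFactors = FALSE)
  }))

  items <- do.call(rbind, lapply(seq_len(nrow(sets)), function(i) {
    t_idx <- true_idx_list[[i]]
    data.frame(item_id = sprintf("%s_i%d", sets$set_id[i], seq_along(t_idx)),
               set_id = sets$set_id[i], size_k = sets$size_k[i],
               sound_id = sets$sound_id[i], practice = sets$practice[i],
               cand_idx = t_idx,
               x = cand_list[[i]][t_idx, 1], y = cand_list[[i]][t_idx, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(items) <- NULL

  design <- structure(list(sets = sets, items = items, candidates = candidates,
                           novel_sound_id = "snd_novel", grid = grid),
                      class = "tmr_design")
  design$items$block <- NA_integer_
  design <- schedule_blocks(design)
  design
}

#' Assign scored items to learning blocks
#'
#' Splits the 90 scored items into six blocks of 15 so that no two items of
#' one set share a block, every six-item set spans all six blocks, and the two
#' items of each two-item set sit in consecutive blocks.
#'
#' @param design A `tmr_design`.
#' @param rng_seed Optional integer seed.
#' @param retry_cap Attempts at a feasible two-item pair allocation.
#' @return The design with `items$block` filled in for non-practice items.
#' @export
schedule_blocks <- function(design, rng_seed = NULL, retry_cap = 10000L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  items <- design$items
  scored <- !items$practice
  six_sets <- unique(items$set_id[scored & items$size_k == 6L])
  two_sets <- unique(items$set_id[scored & items$size_k == 2L])
  one_sets <- unique(items$set_id[scored & items$size_k == 1L])
  n_blocks <- 6L
  per_block <- 15L

  six_load <- length(six_sets)   # one item of each six-item set per block
  ok <- FALSE
  for (att in seq_len(retry_cap)) {
    start_blk <- sample(seq_len(n_blocks - 1L), length(two_sets), replace = TRUE)
    two_load <- tabulate(start_blk, n_blocks) + tabulate(start_blk + 1L, n_blocks)
    single_fill <- per_block - six_load - two_load
    if (all(single_fill >= 0) && sum(single_fill) == length(one_sets)) {
      ok <- TRUE; break
    }
  }
  if (!ok) stop("schedule infeasible: no valid two-item block allocation found")

  blk <- stats::setNames(rep(NA_integer_, nrow(items)), items$item_id)
  for (s in six_sets) {
    idx <- which(items$set_id == s)
    blk[idx] <- sample.int(n_blocks)
  }
  for (j in seq_along(two_sets)) {
    idx <- which(items$set_id == two_sets[j])
    blk[idx] <- sample(c(start_blk[j], start_blk[j] + 1L))
  }
  pool <- sample(rep.int(seq_len(n_blocks), single_fill))
  blk[match(paste0(one_sets, "_i1"), items$item_id)] <- pool
  items$block <- unname(blk)
  design$items <- items
  design
}

# lexicographic balance objective for one candidate cued/non-cued split
.balance_objective <- function(vals, subset_cols) {
  tot <- colSums(vals)
  half <- vals[subset_cols, , drop = FALSE]
  abs(2 * colSums(half) - tot)
}

#' Choose which sets to cue, balancing pre-sleep performance
#'
#' Within each set-size class independently, exactly half the sets are flagged
#' for cueing. The split minimises the absolute difference in pre-sleep
#' incorrect-placement counts between the cued and non-cued halves, breaking
#' ties by the difference in swap-error counts, then by the difference in
#' summed absolute pixel error, then uniformly at random. All C(n, n/2)
#' splits are enumerated.
#'
#' @param set_scores Data frame with columns `set_id`, `size_k`,
#'   `n_incorrect`, `n_swap`, `sum_abs_err` (pre-sleep summaries per set);
#'   practice sets must be excluded by the caller.
#' @param rng_seed Optional integer seed (tie-breaking).
#' @return `set_scores` with an added logical `cued` column.
#' @export
balance_cuing <- function(set_scores, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  set_scores$cued <- NA
  for (k in unique(set_scores$size_k)) {
    idx <- which(set_scores$size_k == k)
    n <- length(idx)
    if (n %% 2L != 0L)
      stop("odd number of sets (", n, ") in size class ", k)
    combs <- .half_splits(n)
    vals <- t(as.matrix(set_scores[idx, c("n_incorrect", "n_swap", "sum_abs_err")]))
    # objective per split, lexicographic over the three criteria
    o1 <- abs(2 * .subset_sums(vals[1, ], combs) - sum(vals[1, ]))
    best <- which(o1 == min(o1))
    if (length(best) > 1L) {
      o2 <- abs(2 * .subset_sums(vals[2, ], combs[, best, drop = FALSE]) - sum(vals[2, ]))
      best <- best[o2 == min(o2)]
      if (length(best) > 1L) {
        o3 <- abs(2 * .subset_sums(vals[3, ], combs[, best, drop = FALSE]) - sum(vals[3, ]))
        best <- best[o3 == min(o3)]
      }
    }
    pick <- if (length(best) > 1L) sample(best, 1L) else best
    cued <- logical(n)
    cued[combs[, pick]] <- TRUE
    set_scores$cued[idx] <- cued
  }
  set_scores
}

# memoised enumeration of n-choose-n/2 index matrices
.split_cache <- new.env(parent = emptyenv())
.half_splits <- function(n) {
  key <- as.character(n)
  if (is.null(.split_cache[[key]]))
    .split_cache[[key]] <- utils::combn(n, n %/% 2L)
  .split_cache[[key]]
}

.subset_sums <- function(v, combs) {
  m <- matrix(v[combs], nrow = nrow(combs))
  colSums(m)
}

#' Build the randomized-blocks sleep cue sequence
#'
#' Each pass is a fresh permutation of the 21 cued sounds plus the novel
#' sound, so repetition counts across sounds never differ by more than one at
#' any truncation point. Inter-cue intervals are drawn uniformly from
#' `iti_choices` and onsets accumulate cue duration plus ITI.
#'
#' @param cued_sounds Data frame with columns `sound_id` and `size_k` for the
#'   cued sets (the novel sound is appended automatically).
#' @param n_passes Number of passes through the full sound list.
#' @param rng_seed Optional integer seed.
#' @param cue_duration_s Sound duration used for onset bookkeeping, seconds.
#' @param iti_choices Possible inter-cue intervals, seconds.
#' @param novel_sound_id Identifier of the never-learned control sound.
#' @param truncate_events Optionally keep only the first so-many events
#'   (emulates cueing stopped mid-pass when the nap ends).
#' @return Data frame (`cue_schedule`): `sound_id`, `size_k`, `pass`,
#'   `rep_idx`, `iti_s`, `onset_s`.
#' @export
build_cue_sequence <- function(cued_sounds, n_passes = 11L, rng_seed = NULL,
                               cue_duration_s = 0.6,
                               iti_choices = c(4.5, 5, 5.5),
                               novel_sound_id = "snd_novel",
                               truncate_events = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sounds <- rbind(cued_sounds[, c("sound_id", "size_k")],
                  data.frame(sound_id = novel_sound_id, size_k = 0L))
  n <- nrow(sounds)
  if (n_passes < 1L) {
    sched <- data.frame(sound_id = character(0), size_k = integer(0),
                        pass = integer(0), rep_idx = integer(0),
                        iti_s = numeric(0), onset_s = numeric(0))
    return(sched)
  }
  rows <- unlist(lapply(seq_len(n_passes), function(p) sample.int(n)))
  sched <- sounds[rows, , drop = FALSE]
  sched$pass <- rep(seq_len(n_passes), each = n)
  sched$iti_s <- sample(iti_choices, n * n_passes, replace = TRUE)
  sched$onset_s <- c(0, cumsum(cue_duration_s + sched$iti_s))[seq_len(n * n_passes)]
  if (!is.null(truncate_events))
    sched <- sched[seq_len(min(truncate_events, nrow(sched))), , drop = FALSE]
  reps <- stats::ave(seq_len(nrow(sched)), sched$sound_id, FUN = seq_along)
  sched$rep_idx <- reps
  rownames(sched) <- NULL
  sched[, c("sound_id", "size_k", "pass", "rep_idx", "iti_s", "onset_s")]
}

#' Write the design tables to CSV
#'
#' @param design A `tmr_design`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_design_csv <- function(design, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(items = file.path(dir, "design_items.csv"),
             sets = file.path(dir, "design_sets.csv"),
             candidates = file.path(dir, "design_candidates.csv"))
  utils::write.csv(design$items, paths["items"], row.names = FALSE)
  utils::write.csv(design$sets, paths["sets"], row.names = FALSE)
  utils::write.csv(design$candidates, paths["candidates"], row.names = FALSE)
  invisible(paths)
}
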