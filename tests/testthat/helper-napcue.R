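# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

test_design <- function() {
  if (is.null(.fixture_env$design))
    .fixture_env$design <- build_design(rng_seed = 20260924L)
  .fixture_env$design
}

test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- run_config(seed = 101L, n_participants = 8L, eeg = FALSE)
    .fixture_env$cohort <- simulate_cohort(test_design(), cfg)
  }
  .fixture_env$cohort
}

test_scored <- function() {
  if (is.null(.fixture_env$scored)) {
    co <- test_cohort()
    .fixture_env$scored <- score_dataset(co$placements, test_design(),
                                         cued_sets = co$cued_sets)
  }
  .fixture_env$scored
}

# independent brute-force audit of one set's candidate points against the
# grid rules (used as the oracle for the sampler)
audit_points <- function(pts, existing, grid) {
  r <- sqrt(rowSums(pts^2))
  if (any(r < grid$min_center_dist - 1e-9)) return("center")
  if (any(r > grid$radius_px - grid$min_border_dist + 1e-9)) return("border")
  for (i in seq_len(nrow(pts) - 1))
    for (j in (i + 1):nrow(pts))
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < grid$min_within_set_dist - 1e-9)
        return("within_set")
  if (nrow(existing))
    for (i in seq_len(nrow(pts)))
      for (j in seq_len(nrow(existing)))
        if (sqrt(sum((pts[i, ] - existing[j, ])^2)) < grid$min_pairwise_dist - 1e-9)
          return("pairwise")
  "ok"
}
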