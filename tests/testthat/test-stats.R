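# independent oracle: stats::aov with Error() strata for a fully
# within-subject two-factor design
aov_oracle <- function(dat) {
  dat$A <- factor(dat$A); dat$B <- factor(dat$B); dat$s <- factor(dat$s)
  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = dat)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- trimws(rownames(tab)) == term
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
      df1 = tab[i, "Df"], df2 = tab[!i, "Df"])
  }
  list(A = grab("Error: s:A", "A"), B = grab("Error: s:B", "B"),
       AB = grab("Error: s:A:B", "A:B"))
}

test_that("rm_anova matches the aov error-strata oracle on random designs", {
  set.seed(21)
  for (rep in 1:5) {
    dat <- expand.grid(s = paste0("s", 1:6), A = c("a1", "a2"),
                       B = c("b1", "b2", "b3"))
    dat$y <- rnorm(nrow(dat), mean = 2 * (dat$A == "a2") + as.integer(dat$B))
    got <- rm_anova(dat, "y", c("A", "B"), subject = "s")
    ora <- aov_oracle(dat)
    for (nm in c("A", "B")) {
      row <- got[got$effect == nm, ]
      expect_equal(row$F, unname(ora[[nm]]["F"]), tolerance = 1e-8)
      expect_equal(row$p, unname(ora[[nm]]["p"]), tolerance = 1e-8)
      expect_equal(row$df1, unname(ora[[nm]]["df1"]))
      expect_equal(row$df2, unname(ora[[nm]]["df2"]))
    }
    row <- got[got$effect == "A:B", ]
    expect_equal(row$F, unname(ora$AB["F"]), tolerance = 1e-8)
    expect_equal(row$p, unname(ora$AB["p"]), tolerance = 1e-8)
  }
})

test_that("rm_anova handles degenerate and invalid inputs", {
  dat <- expand.grid(s = paste0("s", 1:5), A = c("a1", "a2"), B = c("b1", "b2"))
  dat$y <- 3
  got <- rm_anova(dat, "y", c("A", "B"), subject = "s")
  expect_true(all(got$F == 0) && all(got$p == 1))

  # participant-constant shifts are absorbed by the subject term
  dat$y <- as.integer(factor(dat$s)) * 2
  got2 <- rm_anova(dat, "y", c("A", "B"), subject = "s")
  expect_true(all(got2$F == 0))

  expect_error(rm_anova(dat[-1, ], "y", c("A", "B"), subject = "s"),
               "complete and balanced")
})

test_that("tukey_hsd reproduces the studentized-range closed form", {
  same <- tukey_hsd(c(a = 1, b = 1, c = 1), ms_error = 2, df_error = 10, n = 8)
  expect_true(all(same$p == 1))
  means <- c(a = 0, b = 1.5, c = 4)
  got <- tukey_hsd(means, ms_error = 2, df_error = 12, n = 6)
  q_manual <- abs(means["a"] - means["c"]) / sqrt(2 / 6)
  expect_equal(got$q[got$level_1 == "a" & got$level_2 == "c"],
               unname(q_manual))
  expect_equal(got$p, ptukey(got$q, 3, 12, lower.tail = FALSE))
  # widening a gap never increases its p-value
  wider <- tukey_hsd(c(a = 0, b = 1.5, c = 6), ms_error = 2, df_error = 12, n = 6)
  expect_lte(wider$p[3], got$p[3])
  expect_error(tukey_hsd(means, 2, 0, 6), "df_error")
})

test_that("BIC Bayes factor identities hold", {
  expect_equal(bic_bayes_factor(100, 100), 1)
  expect_equal(bic_bayes_factor(100, 102), exp(1))
  set.seed(22)
  for (i in 1:10) {
    b <- rnorm(2, 200, 20)
    expect_equal(bic_bayes_factor(b[1], b[2]) * bic_bayes_factor(b[2], b[1]), 1)
  }
})

test_that("pre-sleep regression adjustment matches the normal equations", {
  set.seed(23)
  pre <- rnorm(20, 100, 30)
  # crafted exact line: residuals vanish, everything shrinks to the mean
  forg <- 2 * pre
  expect_equal(regress_out_presleep(pre, forg), rep(mean(forg), 20))
  # zero slope: adjustment leaves scores unchanged
  forg2 <- rep(5, 20) + 0 * pre
  expect_equal(regress_out_presleep(pre, forg2), forg2)
  # random data: independent closed-form OLS oracle
  forg3 <- 0.5 * pre + rnorm(20, 0, 10)
  X <- cbind(1, pre)
  beta <- solve(t(X) %*% X, t(X) %*% forg3)
  oracle <- forg3 - as.numeric(X %*% beta) + mean(forg3)
  expect_equal(regress_out_presleep(pre, forg3), oracle)
  expect_warning(out <- regress_out_presleep(rep(1, 20), forg3), "zero variance")
  expect_equal(out, forg3)
})

test_that("sample skewness matches the bias-corrected estimator", {
  set.seed(24)
  x <- rnorm(2000)
  expect_equal(napcue:::sample_skewness(x), 0, tolerance = 0.12)
  y <- c(1, 2, 3, 4, 100)
  n <- 5; m <- mean(y)
  g1 <- mean((y - m)^3) / mean((y - m)^2)^1.5
  expect_equal(napcue:::sample_skewness(y), sqrt(n * (n - 1)) / (n - 2) * g1)
})

test_that("ICC estimator and permutation p behave correctly", {
  # identical items within sets, sets differ: perfect agreement in both arms
  b <- rep(c(1, 5, 9, 2, 7, 11), each = 4)
  s <- rep(paste0("g", 1:6), each = 4)
  cu <- rep(c(TRUE, FALSE), each = 12)
  res <- icc_with_permutation(b, s, cu, n_perm = 50, rng_seed = 1)
  expect_equal(res$icc_cued, 1)
  expect_equal(res$icc_noncued, 1)
  expect_equal(res$diff, 0)
  expect_gt(res$p_perm, 0)

  # balanced case agrees with a direct mean-squares oracle
  set.seed(25)
  v <- rnorm(24); g <- rep(1:6, each = 4)
  msb <- 4 * var(tapply(v, g, mean)) # k * var of group means
  msw <- mean(tapply(v, g, var))
  oracle <- (msb - msw) / (msb + 3 * msw)
  expect_equal(napcue:::.icc1(v, g), oracle)

  # unbalanced groups use the n0 coefficient; compare against aov-based MS
  v2 <- rnorm(21); g2 <- rep(1:5, times = c(3, 4, 5, 4, 5))
  a <- anova(lm(v2 ~ factor(g2)))
  msb2 <- a$`Mean Sq`[1]; msw2 <- a$`Mean Sq`[2]
  n0 <- (21 - sum(table(g2)^2) / 21) / 4
  expect_equal(napcue:::.icc1(v2, g2),
               (msb2 - msw2) / (msb2 + (n0 - 1) * msw2))

  expect_error(icc_with_permutation(rep(1, 24), s, cu, n_perm = 10),
               "degenerate")
})

test_that("max-|z| outlier statistic matches hand computation", {
  b <- c(1, 1, 1, 1, 1, 7, rnorm(18))
  s <- rep(paste0("g", 1:4), each = 6)
  cu <- rep(c(TRUE, FALSE), each = 12)
  res <- suppressWarnings(max_abs_z_outlier(b, s, cu))
  expect_equal(res$set_stats$max_abs_z[res$set_stats$set_id == "g1"],
               5 / sqrt(6))
  # affine invariance
  res2 <- suppressWarnings(max_abs_z_outlier(3 * b + 11, s, cu))
  expect_equal(res$set_stats$max_abs_z, res2$set_stats$max_abs_z)
  # degenerate set scores zero with a warning
  b3 <- c(rep(2, 6), rnorm(18))
  expect_warning(res3 <- max_abs_z_outlier(b3, s, cu), "zero within-set SD")
  expect_equal(res3$set_stats$max_abs_z[res3$set_stats$set_id == "g1"], 0)
})

test_that("repetition-benefit correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(repetition_benefit_correlation(2 * x + 1, x)$r, 1)
  set.seed(26)
  b <- rnorm(5); r <- rnorm(5)
  got <- repetition_benefit_correlation(b, r)
  expect_equal(got$r, cov(b, r) / (sd(b) * sd(r)))
  expect_equal(got$p, cor.test(r, b)$p.value)
  expect_error(repetition_benefit_correlation(rep(1, 5), x), "zero variance")
  # probability variant transforms repetitions through the sampling model
  gotp <- repetition_benefit_correlation(b, r + 10, size_k = 6,
                                         use_probability = TRUE)
  expect_equal(gotp$r, cor(reactivation_probability(6, r + 10), b))
})

test_that("familiarity covariate analysis absorbs familiarity confounds", {
  set.seed(27)
  n <- 120
  st <- data.frame(size_k = sample(c(1, 2, 6), n, TRUE),
                   cued = sample(c(TRUE, FALSE), n, TRUE))
  st$familiarity <- rnorm(n, 50, 10)
  # benefit driven purely by familiarity, which is higher for cued sets
  st$familiarity <- st$familiarity + 8 * st$cued
  st$benefit <- 0.9 * st$familiarity + rnorm(n, 0, 1)
  res <- familiarity_covariate_analysis(st)
  expect_gt(res$p[res$effect == "cued"], 0.05)
  # without the covariate the spurious cuing effect is large
  naive <- anova(lm(benefit ~ size_k + cued, st))
  expect_lt(naive["cued", "Pr(>F)"], 0.001)
  # orthogonal familiarity leaves the cuing p essentially unchanged
  st2 <- st
  st2$familiarity <- rnorm(n, 50, 10)
  st2$benefit <- 5 * st2$cued + rnorm(n)
  with_cov <- familiarity_covariate_analysis(st2)
  no_cov <- st2; no_cov$familiarity <- 1
  expect_warning(without <- familiarity_covariate_analysis(no_cov), "constant")
  expect_equal(with_cov$p[with_cov$effect == "cued"],
               without$p[without$effect == "cued"], tolerance = 0.02)
})

test_that("subsample robustness accumulates screened datasets", {
  sc <- test_scored()
  co <- test_cohort()
  items <- sc$items
  rep <- subsample_robustness(items, n_datasets = 25, rng_seed = 31)
  expect_equal(rep$n_kept, 25L)
  expect_length(rep$p_cuing, 25)
  expect_true(all(rep$p_cuing > 0 & rep$p_cuing <= 1))
  expect_true(is.finite(rep$skew_p_interaction))
  # a PRH cohort shows the cued advantage in every kept dataset
  expect_equal(rep$pct_cued_higher, 100)
  # impossible screen hits the attempt cap
  expect_error(subsample_robustness(items, n_datasets = 5, screen_alpha = 1.01,
                                    max_attempts = 40),
               "acceptance too low")
})
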