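# ROC/Youden thresholding, tier classification, the synthetic rated cohort
# and the quartile group comparison.

test_that("Youden threshold matches exhaustive search on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:100, 1)
    x <- round(stats::rnorm(n), 2)
    lab <- stats::rbinom(n, 1, stats::plogis(2 * x)) == 1
    if (all(lab) || !any(lab) || length(unique(x)) < 2) next
    got <- roc_youden_threshold(x, lab)
    ref <- brute_youden(x, lab)
    expect_equal(got$threshold, ref$threshold)
    expect_equal(got$J, ref$J)
  }
})

test_that("separable and interleaved cases behave as expected", {
  got <- roc_youden_threshold(c(0.9, 1.0, 1.2, 1.5), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(got$threshold, 1.1)
  expect_equal(got$J, 1.0)
  # perfectly interleaved equal classes: no cut beats J = 0 by construction
  x <- seq(0.1, 1.6, by = 0.1)
  lab <- rep(c(FALSE, TRUE), 8)
  expect_lte(roc_youden_threshold(x, lab)$J, 0.25)
  expect_equal(brute_youden(x, lab)$J, roc_youden_threshold(x, lab)$J)
  # flipped labels with the complementary direction give the mirrored rule
  flip <- roc_youden_threshold(c(0.9, 1.0, 1.2, 1.5),
                               c(TRUE, TRUE, FALSE, FALSE),
                               direction = "leq")
  expect_equal(flip$threshold, 1.1)
  expect_equal(flip$J, 1.0)
  expect_error(roc_youden_threshold(1:4, rep(TRUE, 4)), "both classes")
})

test_that("tier classification partitions the SUVR line with closed-left bounds", {
  thr <- tier_thresholds(1.07, 1.34)
  expect_equal(as.character(classify_tier(1.00, thr)), "Low")
  expect_equal(as.character(classify_tier(1.07, thr)), "Moderate")
  expect_equal(as.character(classify_tier(1.33, thr)), "Moderate")
  expect_equal(as.character(classify_tier(1.34, thr)), "High")
  expect_equal(as.character(classify_tier(1.50, thr)), "High")
  v <- seq(0.5, 2.2, by = 0.01)
  tiers <- classify_tier(v, thr)
  expect_false(any(is.na(tiers)))  # exactly one tier per value
  expect_error(tier_thresholds(1.4, 1.3), "below")
})

test_that("the synthetic rated cohort is reproducible and identifiable without noise", {
  a <- generate_synthetic_ratings(100, seed = 5)
  b <- generate_synthetic_ratings(100, seed = 5)
  expect_identical(a, b)
  expect_error(generate_synthetic_ratings(10), "n >= 20")
  # noiseless link: ratings are a deterministic step function of SUVR and
  # the recovered cuts classify identically to the generating cuts
  coh <- generate_synthetic_ratings(400, seed = 8, noise_sd = 0)
  cuts <- c(1.07, 1.34)
  expect_true(all((coh$rating >= 2) == (coh$meninges_suvr >= cuts[1])))
  expect_true(all((coh$rating >= 4) == (coh$meninges_suvr >= cuts[2])))
  thr <- recover_tier_thresholds(coh)
  expect_equal(thr$youden_moderate, 1)
  expect_equal(thr$youden_high, 1)
  got <- classify_tier(coh$meninges_suvr, thr)
  want <- classify_tier(coh$meninges_suvr, tier_thresholds(cuts[1], cuts[2]))
  expect_equal(got, want)
  # the recovered cut lies inside the data gap straddling the true cut
  below <- max(coh$meninges_suvr[coh$meninges_suvr < cuts[1]])
  above <- min(coh$meninges_suvr[coh$meninges_suvr >= cuts[1]])
  expect_gt(thr$moderate_cut, below)
  expect_lte(thr$moderate_cut, above)
})

test_that("generating cutpoints are recovered within 0.05 under consistent-rater noise", {
  # the Youden cut is biased low by roughly the latent noise SD when the
  # marker density falls across the cut, so recovery to +/-0.05 needs a
  # rater-consistency noise level (sigma = 0.02 SUVR, ~15% of a rating bin)
  errs <- t(vapply(1:100, function(s) {
    coh <- generate_synthetic_ratings(433, seed = s, noise_sd = 0.02)
    thr <- recover_tier_thresholds(coh)
    c(thr$moderate_cut - 1.07, thr$high_cut - 1.34)
  }, numeric(2)))
  expect_lt(stats::quantile(abs(errs[, 1]), 0.95), 0.05)
  expect_lt(stats::quantile(abs(errs[, 2]), 0.95), 0.05)
  expect_lt(mean(abs(errs)), 0.03)
})

test_that("tier fractions on a cohort drawn at the clinical distribution are plausible", {
  coh <- generate_synthetic_ratings(4000, seed = 12, noise_sd = 0.08)
  tiers <- classify_tier(coh$meninges_suvr, tier_thresholds(1.07, 1.34))
  frac <- as.vector(prop.table(table(tiers)))
  # the clinical split is roughly 65/24/11; the generator's truncated
  # lognormal puts ~65/27/9 across the cuts
  expect_lt(abs(frac[1] - 0.65), 0.05)
  expect_lt(abs(frac[2] - 0.27), 0.05)
  expect_lt(abs(frac[3] - 0.09), 0.04)
})

test_that("quartile partition and degenerate cohorts behave as documented", {
  q8 <- quartile_group_test(1:8, rep(c(1, 1.05), 4))
  expect_equal(as.vector(q8$quartiles$n), rep(2, 4))
  expect_equal(q8$quartile_assignment, rep(1:4, each = 2))
  const <- quartile_group_test(seq(0.8, 2.2, length.out = 16), rep(1.1, 16))
  expect_equal(const$slope_before, 0)
  expect_true(all(is.na(const$tests$p_before) | const$tests$p_before > 0.05))
  expect_error(quartile_group_test(1:4, 1:4), "at least 8")
})

test_that("SCF removes a generated sinus-ERC association in the quartile test", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 120
    sinus <- pmax(stats::rnorm(n, 1.38, 0.34), 0.7)
    erc <- 0.9 + (0.22 * sinus - 0.75 / 8.36) + stats::rnorm(n, 0, 0.05)
    qt <- quartile_group_test(sinus, erc)
    c(slope = qt$slope_after,
      sig_before = qt$tests$p_before[3] < 0.05,
      sig_after = qt$tests$p_after[3] < 0.05)
  }, numeric(3))
  expect_lt(stats::quantile(abs(hits["slope", ]), 0.95), 0.03)
  expect_gt(mean(hits["sig_before", ]), 0.95)  # association detected pre-correction
  # removal is exact, so post-correction p-values are uniform and the
  # non-significant rate is nominally 95%; allow binomial fluctuation
  expect_gte(mean(1 - hits["sig_after", ]), 0.90)
})
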