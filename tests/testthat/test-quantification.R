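# SUV/SUVR arithmetic, ROI statistics, percent differences, longitudinal
# change and the correlation/fit helpers.

make_img <- function(values, vs = c(1, 1, 1), unit = "kBq/mL") {
  pet_image(values, voxel_grid(dim(values), vs), unit)
}

test_that("SUV conversion follows dose-per-weight unit arithmetic", {
  d <- c(4, 4, 4)
  img <- make_img(array(6.16667, d))
  expect_equal(to_suv(img)$values[1], 1, tolerance = 1e-5)
  expect_equal(to_suv(make_img(array(0, d)))$values[1], 0)
  # the calibration identity: 51.553 kBq/mL -> SUV 8.36
  conc <- default_reference_concentration()
  expect_equal(to_suv(make_img(array(conc, d)))$values[1], 8.36)
  # linear in concentration, inverse in dose
  expect_equal(to_suv(make_img(array(12.33334, d)))$values[1], 2,
               tolerance = 1e-5)
  expect_equal(to_suv(img, injected_dose_MBq = 740)$values[1], 0.5,
               tolerance = 1e-5)
  expect_error(to_suv(to_suv(img)), "kBq/mL")
})

test_that("ROI statistics use the sample SD convention", {
  d <- c(4, 4, 4)
  vals <- array(5, d)
  msk <- array(FALSE, d); msk[1:2, 1, 1] <- TRUE
  s <- roi_mean(make_img(vals), msk)
  expect_equal(s$mean, 5); expect_equal(s$sd, 0); expect_equal(s$n, 2)
  vals[1, 1, 1] <- 1; vals[2, 1, 1] <- 3
  s2 <- roi_mean(make_img(vals), msk)
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(((1 - 2)^2 + (3 - 2)^2) / (2 - 1)))  # sample, not population
  full <- array(TRUE, d)
  expect_equal(roi_mean(make_img(vals), full)$mean, mean(vals))
  expect_error(roi_mean(make_img(vals), array(FALSE, d)), "empty")
})

test_that("SUVR is one in the reference region and scale invariant", {
  d <- c(6, 6, 6)
  set.seed(3)
  vals <- array(stats::runif(prod(d), 1, 10), d)
  ref <- array(FALSE, d); ref[1:3, 1:3, 1:3] <- TRUE
  suvr <- compute_suvr(make_img(vals), ref)
  expect_equal(mean(suvr$values[ref]), 1)
  scaled <- compute_suvr(make_img(7.7 * vals), ref)
  expect_equal(scaled$values, suvr$values, tolerance = 1e-12)
  expect_error(compute_suvr(make_img(array(0, d)), ref), "positive")
})

test_that("percent differences reproduce the reference-table arithmetic", {
  expect_equal(round(percent_delta(12.99, 7.74), 1), 67.8)
  expect_equal(round(percent_delta(8.97, 8.36), 1), 7.3)
  expect_equal(percent_delta(5, 5), 0)
  expect_equal(percent_delta(4, 5, signed = TRUE), -20)
  expect_equal(percent_delta(4, 5), 20)
  expect_error(percent_delta(1, 0), "baseline")
})

test_that("longitudinal change matches the folded-normal closed form", {
  lc <- longitudinal_change(1.0, 1.1)
  expect_equal(lc$signed_mean, 10, tolerance = 1e-9)
  expect_equal(lc$abs_mean, 10, tolerance = 1e-9)
  lc2 <- longitudinal_change(c(1, 1), c(1.1, 0.9))
  expect_equal(lc2$signed_mean, 0, tolerance = 1e-9)
  expect_equal(lc2$abs_mean, 10, tolerance = 1e-9)
  # cohort drawn at the clinical sinus signed-change parameters:
  # absolute mean approaches the folded-normal expectation
  mu <- 0.9; s <- 17.9
  folded <- s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / s))
  set.seed(21)
  ch <- stats::rnorm(20000, mu, s)
  lc3 <- longitudinal_change(rep(1, 20000), 1 + ch / 100)
  expect_equal(lc3$abs_mean, folded, tolerance = 0.02)
  expect_gt(lc3$frac_beyond_10, 0.4)  # near half the cohort moves > 10%
  expect_gte(lc3$abs_mean, abs(lc3$signed_mean))
  expect_error(longitudinal_change(c(1, -1), c(1, 1)), "positive")
})

test_that("correlation and OLS agree with direct formula evaluation", {
  set.seed(5)
  for (rep in 1:10) {
    x <- stats::rnorm(4); y <- stats::rnorm(4)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), r_direct, tolerance = 1e-12)
    slope_direct <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    fit <- linear_fit(x, y)
    expect_equal(fit$slope, slope_direct, tolerance = 1e-12)
    expect_equal(fit$intercept, mean(y) - slope_direct * mean(x),
                 tolerance = 1e-12)
  }
  expect_equal(pearson_r(1:5, 2 * (1:5) + 3), 1)
  expect_equal(linear_fit(c(0, 1), c(1, 3)), list(slope = 2, intercept = 1, r = 1))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(linear_fit(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("reference group means yield the published spill-in fits", {
  g <- ecb_group_suv()
  b <- g[g$group == "BKG", ]
  expect_equal(round(pearson_r(g$meninges,
                               percent_delta(g$cerebellum, b$cerebellum)), 2),
               0.99)
  expect_equal(round(pearson_r(g$sinus, percent_delta(g$erc, b$erc)), 2),
               0.97)
  expect_equal(round(linear_fit(g$sinus, g$erc)$slope, 2), 0.22)
  expect_equal(round(linear_fit(g$meninges, g$cerebellum)$slope, 2), 0.14)
})

test_that("alternative reference regions are progressively less meninges-sensitive", {
  # needs voxels finer than the 3 mm cerebellar erosion radius
  ph <- build_phantom(phantom_spec(shape = c(64, 64, 64),
                                   voxel_size = c(3, 3, 3)))
  sc <- scanner_model(grid = ph$grid)
  m <- phantom_masks(ph)
  profs <- c("BKG", "LOW", "AVG", "HIGH", "H_MENINGES", "H_SINUS")
  suvs <- t(vapply(profs, function(nm) {
    em <- build_emission_map(ph, calibrate_ecb_activities(ecb_profile(nm), ph))
    img <- to_suv(simulate_noiseless(em, sc))
    c(men = roi_mean(img, m$meninges_shell)$mean,
      cer = roi_mean(img, m$inferior_cerebellum)$mean,
      ecer = roi_mean(img, m$eroded_inferior_cerebellum)$mean,
      wm = roi_mean(img, m$eroded_white_matter)$mean)
  }, numeric(4)))
  slope_cer <- linear_fit(suvs[, "men"], suvs[, "cer"])$slope
  slope_ecer <- linear_fit(suvs[, "men"], suvs[, "ecer"])$slope
  expect_lt(slope_ecer, slope_cer)
  wm_spread <- (max(suvs[, "wm"]) - min(suvs[, "wm"])) / min(suvs[, "wm"])
  expect_lt(wm_spread, 0.01)
})
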