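# Forward model: blurring, decay, Poisson statistics, reconstruction,
# realization reproducibility.

test_that("Gaussian blur preserves constants in the interior and FWHM 0 is identity", {
  d <- c(24, 24, 24)
  vol <- array(3.7, d)
  out <- psf_blur(vol, c(6, 6, 6), c(2, 2, 2))
  expect_equal(out[9:16, 9:16, 9:16], vol[9:16, 9:16, 9:16],
               tolerance = 1e-9)
  expect_identical(psf_blur(vol, 0, c(2, 2, 2)), vol)
})

test_that("blurred impulse has the requested FWHM within half a voxel", {
  d <- c(33, 33, 33)
  vol <- array(0, d)
  vol[17, 17, 17] <- 1
  fwhm <- c(7.3, 7.3, 7.4)
  vs <- c(2, 2, 2)
  out <- psf_blur(vol, fwhm, vs)
  profile <- out[, 17, 17]
  half <- max(profile) / 2
  above <- which(profile >= half)
  measured <- (max(above) - min(above) + 1) * vs[1]
  expect_lt(abs(measured - fwhm[1]), vs[1])
  # direct Gaussian evaluation at the peak and one-off voxel
  sigma <- fwhm[1] / (2 * sqrt(2 * log(2)))
  expect_equal(profile[18] / profile[17], exp(-vs[1]^2 / (2 * sigma^2)),
               tolerance = 1e-6)
})

test_that("FFT convolution matches the direct shift-and-add oracle", {
  set.seed(11)
  d <- c(10, 9, 8)
  x <- array(stats::rnorm(prod(d)), d)
  k <- ecbspill:::gaussian_kernel(c(4, 5, 6), c(2, 2, 2))
  expect_equal(ecbspill:::fft_convolve3(x, k), brute_convolve(x, k),
               tolerance = 1e-10)
})

test_that("frame decay factor equals the quadrature of the decay integrand", {
  for (start in c(0, 4200)) {
    q <- stats::integrate(function(t) 2^(-t / 6586.2), start, start + 300,
                          rel.tol = 1e-12)$value / 300
    expect_equal(decay_factor(start, 300, 6586.2), q, tolerance = 1e-9)
  }
})

test_that("noiseless simulation of a uniform field returns the field in the interior", {
  ph <- test_phantom()
  sc <- test_scanner()
  cal <- test_calibration("BKG")
  em <- build_emission_map(ph, cal)
  # set every region to one concentration; interior voxels must equal it
  em$conc[] <- 10
  nl <- simulate_noiseless(em, sc)
  interior <- erode_mm(region_mask(ph, "white_matter"), 12,
                       ph$grid$voxel_size)
  expect_equal(mean(nl$values[interior]), 10, tolerance = 1e-6)
  expect_lt(max(abs(nl$values[interior] - 10)), 1e-4)
})

test_that("seeded noisy frames converge to the noiseless frame at the Poisson rate", {
  ph <- test_phantom()
  sc <- test_scanner()
  em <- build_emission_map(ph, test_calibration("AVG"))
  sch <- frame_schedule()
  nl <- simulate_frame(em, sc, sch, 1, noiseless = TRUE)
  n <- 100
  acc <- array(0, dim(nl$values))
  for (i in seq_len(n))
    acc <- acc + simulate_frame(em, sc, sch, 1, seed = 100 + i)$values
  acc <- acc / n
  interior <- test_masks()$white_matter
  scale <- prod(sc$grid$voxel_size) / 1000 * sc$sensitivity * 300 *
    decay_factor(4200, 300, 6586.2)
  expected_counts <- nl$values[interior] * scale
  rel_dev <- abs(acc[interior] - nl$values[interior]) / nl$values[interior]
  bound <- 3 / sqrt(expected_counts * n)
  expect_lt(mean(rel_dev > bound), 0.01)
})

test_that("reconstruction averages frames and quarters the variance over four", {
  ph <- test_phantom()
  sc <- test_scanner()
  em <- build_emission_map(ph, test_calibration("AVG"))
  sch <- frame_schedule()
  f1 <- simulate_frame(em, sc, sch, 1, seed = 1)
  expect_equal(reconstruct_scan(list(f1))$values, f1$values)
  same <- reconstruct_scan(list(f1, f1, f1, f1))
  expect_equal(same$values, f1$values, tolerance = 1e-12)
  # variance of the 4-frame mean ~ single-frame variance / 4 at one voxel set
  m <- test_masks()$erc
  single <- vapply(1:60, function(s)
    mean(simulate_frame(em, sc, sch, 1, seed = s)$values[m]), numeric(1))
  four <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    frames <- lapply(1:4, function(k) simulate_frame(em, sc, sch, k))
    mean(reconstruct_scan(frames)$values[m])
  }, numeric(1))
  ratio <- stats::var(four) / stats::var(single)
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 0.6)  # consistent with ~1/4 up to sampling noise
})

test_that("realizations are seed-reproducible and linear in the emission scale", {
  ph <- test_phantom()
  sc <- test_scanner()
  em <- build_emission_map(ph, test_calibration("AVG"))
  a <- run_realizations(em, sc, n = 2, base_seed = 9)
  b <- run_realizations(em, sc, n = 2, base_seed = 9)
  expect_identical(a[[1]]$values, b[[1]]$values)
  expect_identical(a[[2]]$values, b[[2]]$values)
  expect_equal(attr(a, "seeds"), c(10, 11))
  # n = 1 reproduces the manual simulate-and-reconstruct path
  set.seed(10)
  sch <- frame_schedule()
  frames <- lapply(seq_along(sch$starts), function(k)
    simulate_frame(em, sc, sch, k))
  manual <- reconstruct_scan(frames)
  expect_equal(run_realizations(em, sc, n = 1, base_seed = 9)[[1]]$values,
               manual$values)
  # noiseless linearity: scaling concentrations scales the image
  em2 <- em
  em2$conc <- 2.5 * em$conc
  expect_equal(simulate_noiseless(em2, sc)$values,
               2.5 * simulate_noiseless(em, sc)$values, tolerance = 1e-10)
})

test_that("invalid simulator inputs fail loudly", {
  ph <- test_phantom()
  sc <- test_scanner()
  em <- build_emission_map(ph, test_calibration("BKG"))
  em$conc["1"] <- -1
  expect_error(simulate_noiseless(em, sc), "negative")
  expect_error(frame_schedule(starts = c(0, 100), durations = c(200, 100)),
               "overlap")
  f1 <- simulate_frame(build_emission_map(ph, test_calibration("BKG")),
                       sc, frame_schedule(), 1, noiseless = TRUE)
  g2 <- pet_image(array(0, c(8, 8, 8)), voxel_grid(c(8, 8, 8), c(1, 1, 1)))
  expect_error(reconstruct_scan(list(f1, g2)), "grid mismatch")
})
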