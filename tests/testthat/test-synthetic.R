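test_that("synthetic IRF is a unit-area Gaussian of the requested width", {
  irf <- make_irf(fwhm = 50, t0 = 150, bin_width = 2, max_time = 600)
  expect_equal(sum(irf$value) * 2, 1, tolerance = 1e-9)
  # numerical FWHM
  half <- max(irf$value) / 2
  above <- range(irf$time_ps[irf$value >= half])
  expect_lte(abs(diff(above) - 50), 2)               # within one bin
  expect_equal(irf$time_ps[which.max(irf$value)], 149)
  # zero-width limit: single-bin impulse
  imp <- make_irf(fwhm = 1e-9, t0 = 100, bin_width = 2, max_time = 300)
  expect_identical(sum(imp$value > 0), 1L)
  expect_equal(sum(imp$value) * 2, 1, tolerance = 1e-12)
})

test_that("noiseless synthesis with a delta IRF is proportional to the input", {
  tt <- dgamma(seq(0, 10, length.out = 150), 3, 1.5)
  ftpsf <- tc_grid(tt)
  imp <- make_irf(fwhm = 1e-9, t0 = 1, bin_width = 2, max_time = 300)
  p <- synthetic_ftr_params(coupling = 1, t_shift = 0, peak_counts = 1000)
  out <- synthesize_ftr(ftpsf, imp, p, seed = 1, noise = FALSE)
  expect_equal(out$value / max(out$value), tt / max(tt), tolerance = 1e-9)
  expect_equal(max(out$value), 1000)
})

test_that("the shot-noise stage is Poisson and seed-deterministic", {
  tt <- rep(1, 60); tt[30] <- 5
  ftpsf <- tc_grid(tt)
  irf <- make_irf(fwhm = 20, t0 = 30, bin_width = 2, max_time = 120)
  p <- synthetic_ftr_params(t_shift = 0, peak_counts = 50)
  draws <- vapply(1:2000, function(s)
    synthesize_ftr(ftpsf, irf, p, seed = s)$value[30], 0)
  m <- mean(draws)
  # Poisson: variance ~ mean within a 3 sigma band for the variance estimate
  se_var <- sqrt(2 * m^2 / (length(draws) - 1) + 4 * m^3 / length(draws))
  expect_lt(abs(var(draws) - m), 3 * se_var + 3 * sqrt(m))
  a <- synthesize_ftr(ftpsf, irf, p, seed = 77)
  b <- synthesize_ftr(ftpsf, irf, p, seed = 77)
  expect_identical(a$value, b$value)
})

test_that("the stochastic time shift is recovered by cross-correlation", {
  tt <- c(rep(0, 30), dgamma(seq(0, 8, length.out = 90), 4, 2), rep(0, 30))
  ftpsf <- tc_grid(tt)
  irf <- make_irf(fwhm = 30, t0 = 80, bin_width = 2, max_time = 300)
  p0 <- synthetic_ftr_params(t_shift = 0, peak_counts = 1e5)
  p25 <- synthetic_ftr_params(t_shift = 25, peak_counts = 1e5)
  a <- synthesize_ftr(ftpsf, irf, p0, seed = 5, noise = FALSE)
  b <- synthesize_ftr(ftpsf, irf, p25, seed = 5, noise = FALSE)
  cc <- stats::ccf(b$value, a$value, lag.max = 30, plot = FALSE)
  lag <- cc$lag[which.max(cc$acf)] * 2               # bins -> ps
  expect_lte(abs(lag - 25), 2)
})

test_that("fixture bundles are complete, correct and bitwise reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  grid <- voxel_grid(c(24L, 24L, 16L), 0.5)
  ph <- make_phantom(grid, study_medium(), study_fluor(),
                     cylinder_shape(c(0, 6, 3.5), radius = 1, axis = 1L))
  pat <- scan_pattern(2L, 2L, 0.5, origin = c(4, 5.5))
  probe <- probe_geometry()
  man1 <- make_fixture(dir1, ph, pat, probe, build_strategy2(),
                       n_histories = 2000, seed = 3, max_time = 240)
  # 2 x 2 positions x 3 offsets curves of each kind
  expect_length(man1$files$ftr, 12L)
  expect_length(man1$files$ftpsf, 12L)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(all(file.exists(file.path(dir1, man1$files$ftr))))

  # ground-truth FPDF volumes equal the closed form on the phantom maps
  for (m in seq_along(man1$velocities)) {
    truth <- read_volume(file.path(dir1, man1$files$fpdf_truth[m]))$values
    expect_equal(truth, fpdf_truth(ph, man1$velocities[m]), tolerance = 1e-6)
  }
  f_in <- fpdf_value(ph$medium, ph$fluor, man1$velocities[1])
  truth1 <- read_volume(file.path(dir1, man1$files$fpdf_truth[1]))$values
  expect_equal(max(truth1), f_in, tolerance = 1e-6)

  # manifest replay: identical seeds and parameters give identical files
  man2 <- make_fixture(dir2, ph, pat, probe, build_strategy2(),
                       n_histories = 2000, seed = 3, max_time = 240)
  for (f in c(man1$files$ftr[1:3], man1$files$ftpsf[1:3], "irf.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
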