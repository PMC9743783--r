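test_that("strategy 1 reproduces the published bookkeeping", {
  s1 <- build_strategy1(c(3.3, 2.2, 1.1), 200)
  expect_length(s1$entries, 3L)
  for (m in 1:3) {
    e <- s1$entries[[m]]
    expect_equal(as.numeric(e$gates), 200)
    expect_identical(e$expected_links_per_position, 1L)
  }
  expect_equal(vapply(s1$entries, `[[`, 0, "velocity"),
               c(0.0165, 0.011, 0.0055))
  # 19 x 19 scan: J = 361 per reconstruction
  expect_equal(19 * 19 * s1$entries[[1]]$expected_links_per_position, 361)
  expect_error(build_strategy1(c(3.3, 3.3), 200), "duplicate")
  expect_equal(build_strategy1(1.0, 100)$entries[[1]]$velocity, 0.01)
})

test_that("strategy 2 reproduces the published gates, velocities and counts", {
  s2 <- build_strategy2(c(3.3, 2.2, 1.1), 200)
  e <- s2$entries
  expect_equal(e[[1]]$used_sr_distances, c(3.3, 2.2, 1.1))
  expect_equal(as.numeric(e[[1]]$gates), c(200, 133, 66))
  expect_equal(e[[2]]$used_sr_distances, c(2.2, 1.1))
  expect_equal(as.numeric(e[[2]]$gates), c(200, 100))
  expect_equal(e[[3]]$used_sr_distances, c(3.3, 2.2))
  expect_equal(as.numeric(e[[3]]$gates), c(100, 66))
  expect_equal(vapply(e, `[[`, 0, "velocity"), c(0.0165, 0.011, 0.033))
  # 19 x 19 scan: J = {1083, 722, 722}
  expect_equal(361 * vapply(e, `[[`, 0L, "expected_links_per_position"),
               c(1083L, 722L, 722L))
  # exact (unrounded) gates satisfy R/t = const within 1e-9
  for (m in 1:3) {
    v <- e[[m]]$used_sr_distances / e[[m]]$gate_exact
    expect_lt(diff(range(v)), 1e-9)
    expect_equal(v[[1]], e[[m]]$velocity, tolerance = 1e-12)
  }
  expect_error(build_strategy2(c(3.3, 2.2), 200), "three")
})

fake_sens <- function(grid, link, gate, fill) {
  v <- array(fill, dim = grid$shape)
  structure(v, class = c("sensitivity_volume", "array"), grid = grid,
            link = as_link(link), gate = gate, n_histories = 1,
            seed = 1L)
}

test_that("assembly builds W and g in row order with gate checking", {
  grid <- voxel_grid(c(4L, 4L, 2L), 0.5)
  entry <- build_strategy2()$entries[[2]]   # R = {2.2, 1.1}, gates {200, 100}
  l1 <- list(sx = 0.2, sy = 1, dx = 2.4, dy = 1, sr_distance = 2.2)
  l2 <- list(sx = 0.2, sy = 1, dx = 1.3, dy = 1, sr_distance = 1.1)
  s1 <- fake_sens(grid, l1, 200, 1); s2 <- fake_sens(grid, l2, 100, 2)
  sys <- assemble(list(s1, s2), c(3, 5), entry, calibration = 2)
  expect_identical(dim(sys$W), c(2L, 32L))
  expect_equal(sys$W[1, ], rep(1, 32))
  expect_equal(sys$g, c(6, 10))
  expect_equal(sys$meta$sr_distance, c(2.2, 1.1))
  # one link, one gate -> 1 x I system
  e1 <- build_strategy1(2.2, 200)$entries[[1]]
  sys1 <- assemble(list(s1), 4, e1, calibration = 0.5)
  expect_identical(nrow(sys1$W), 1L)
  expect_equal(sys1$g, 2)
  # wrong gate or distance is rejected
  expect_error(assemble(list(fake_sens(grid, l1, 133, 1)), 1, e1), "gate")
  l3 <- list(sx = 0, sy = 1, dx = 3.3, dy = 1, sr_distance = 3.3)
  expect_error(assemble(list(fake_sens(grid, l3, 200, 1)), 1, e1),
               "not used")
})

test_that("row replication is a pure whole-voxel translation", {
  grid <- voxel_grid(c(6L, 8L, 4L), 0.1)
  set.seed(61)
  link <- list(sx = 0.2, sy = 0.3, dx = 0.5, dy = 0.3, sr_distance = 0.3)
  vol <- fake_sens(grid, link, 200, 0)
  vol[] <- array(runif(prod(grid$shape)), dim = grid$shape)
  # zero shift: identity
  expect_equal(as.numeric(replicate_rows(vol, 0)), as.numeric(vol))
  # +0.5 mm at 0.1 mm voxels: (i, j, k) -> (i, j + 5, k)
  sh <- replicate_rows(vol, 0.5, axis = 2L)
  expect_equal(unclass(sh)[, 6:8, ], unclass(vol)[, 1:3, ], tolerance = 1e-12)
  expect_true(all(unclass(sh)[, 1:5, ] == 0))
  # link metadata moves with the volume
  expect_equal(attr(sh, "link")$sy, 0.8)
  # interior-shift mass conservation
  vol2 <- fake_sens(grid, link, 200, 0)
  vol2[, 3:4, ] <- 1
  expect_equal(sum(replicate_rows(vol2, 0.2, axis = 2L)), sum(vol2))
  # fractional shifts rejected unless rounding is allowed
  expect_error(replicate_rows(vol, 0.25), "whole number")
  expect_silent(replicate_rows(vol, 0.25, round_shift = TRUE))
})

test_that("calibration brings measurements onto the model scale per group", {
  grid <- voxel_grid(c(3L, 3L, 1L), 1)
  e <- build_strategy2()$entries[[2]]
  mk <- function(R, gate, fill) {
    l <- list(sx = 0, sy = 0, dx = R, dy = 0, sr_distance = R)
    fake_sens(grid, l, gate, fill)
  }
  vols <- list(mk(2.2, 200, 2), mk(2.2, 200, 2), mk(1.1, 100, 4))
  f_ref <- array(1e-3, dim = grid$shape)
  pred <- c(2, 2, 4) * 9 * 1e-3
  meas <- c(10, 14, 40)  # arbitrary counts units
  sys <- calibrate_system(assemble(vols, meas, e), f_ref)
  # group sums match after calibration
  expect_equal(sum(sys$g[1:2]), sum(pred[1:2]))
  expect_equal(sys$g[3], pred[3])
  # within-group relative structure is preserved
  expect_equal(sys$g[1] / sys$g[2], 10 / 14)
})

test_that("symmetric-mode assembly reuses one centred kernel per distance", {
  # a single centred kernel translated to each scan position, then scaled by
  # the amplitude factor, yields identical rows up to translation
  grid <- voxel_grid(c(10L, 6L, 3L), 0.5)
  link <- list(sx = 2.0, sy = 1.5, dx = 3.1, dy = 1.5, sr_distance = 1.1)
  kernel <- fake_sens(grid, link, 200, 0)
  kernel[4:6, 3:4, 2] <- 3
  rows <- lapply(c(0, 0.5, 1), function(s)
    replicate_rows(kernel, s, axis = 1L, round_shift = TRUE))
  amp <- 2.5
  e1 <- build_strategy1(1.1, 200)$entries[[1]]
  sys <- assemble(rows, rep(1, 3), e1, calibration = amp)
  expect_equal(sum(sys$W[1, ] > 0), sum(sys$W[3, ] > 0))
  expect_equal(sort(sys$W[1, sys$W[1, ] > 0]), sort(sys$W[2, sys$W[2, ] > 0]))
  expect_equal(sys$g, rep(amp, 3))
})
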