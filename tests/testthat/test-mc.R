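# Monte Carlo engine validation against independent oracles. Trace mode
# exposes raw trajectories so weights and timing can be recomputed in R.

test_that("voxel traversal matches trivial and dense-sampling oracles", {
  grid <- voxel_grid(c(20L, 20L, 20L), 0.1)
  # axis-aligned unit segment starting on a boundary: ten 0.1-mm pieces
  tr <- traverse_voxels(c(0.5, 0.55, 0.55), c(1.5, 0.55, 0.55), grid)
  expect_identical(nrow(tr), 10L)
  expect_equal(tr$length, rep(0.1, 10), tolerance = 1e-9)
  expect_identical(tr$ix, 6:15)
  expect_equal(sum(tr$length), 1, tolerance = 1e-9)
  # degenerate segment
  expect_identical(nrow(traverse_voxels(c(1, 1, 1), c(1, 1, 1), grid)), 0L)
  expect_error(traverse_voxels(c(-5, 0, 0), c(1, 1, 1), grid), "outside")

  # oblique random segments vs a dense point-sampling oracle
  set.seed(31)
  for (k in 1:8) {
    p0 <- runif(3, 0.2, 1.8); p1 <- runif(3, 0.2, 1.8)
    tr <- traverse_voxels(p0, p1, grid)
    len <- sqrt(sum((p1 - p0)^2))
    expect_equal(sum(tr$length), len, tolerance = 1e-9)
    ns <- 10000
    ts <- (seq_len(ns) - 0.5) / ns
    pts <- outer(ts, p1 - p0) + rep(p0, each = ns)
    key <- paste(floor(pts[, 1] / 0.1) + 1, floor(pts[, 2] / 0.1) + 1,
                 floor(pts[, 3] / 0.1) + 1)
    oracle <- table(key) / ns * len
    got <- tapply(tr$length, paste(tr$ix, tr$iy, tr$iz), sum)
    for (nm in names(got))
      expect_lt(abs(got[[nm]] - ifelse(nm %in% names(oracle),
                                       oracle[[nm]], 0)), 1e-3)
  }
})

test_that("launch sampling respects the fiber geometry and angular model", {
  m <- mc_sample_launch(100000L, 0.2, 8.2 * pi / 180, 0.5 * 8.2 * pi / 180, 5L)
  theta <- acos(m[, "uz"])
  expect_true(all(theta <= 8.2 * pi / 180 + 1e-12))   # truncation
  r <- sqrt(m[, "x"]^2 + m[, "y"]^2)
  expect_true(all(r <= 0.2 + 1e-12))
  # uniform disk: E[r] = 2/3 R, sd(r) known; 3 sigma band
  se <- sqrt(0.2^2 / 18) / sqrt(nrow(m))
  expect_lt(abs(mean(r) - 2 / 3 * 0.2), 3 * se)
  # zero-diameter fiber launches on the centre
  m0 <- mc_sample_launch(100L, 0, 8.2 * pi / 180, 0.05, 6L)
  expect_true(all(m0[, "x"] == 0 & m0[, "y"] == 0))
})

test_that("Henyey-Greenstein sampling has the exact first moment", {
  for (g in c(0.62, 0.0, 0.9)) {
    cs <- mc_sample_hg(100000L, g, 9L)
    # var(cos) for HG has no simple closed form; use the sample se
    se <- sd(cs) / sqrt(length(cs))
    expect_lt(abs(mean(cs) - g), 3 * se)
    expect_true(all(abs(cs) <= 1))
  }
})

test_that("ballistic timing and Beer-Lambert attenuation are exact", {
  # near-ballistic medium, straight crossing of the 4-mm slab
  grid <- voxel_grid(c(20L, 20L, 16L), 0.25)
  med <- optical_medium(mua = 0.05, mus = 1e-9, g = 0, n = 1.521)
  ph <- make_phantom(grid, med, study_fluor(),
                     cylinder_shape(c(0, 2.5, 2), radius = 0, axis = 1L))
  probe <- probe_geometry(fiber_diameter = 1e-9, critical_angle = 1e-7)
  link <- list(sx = 2.5, sy = 2.5, dx = 2.5 + 1.1, dy = 2.5,
               sr_distance = 1.1)
  tr <- trace_history(ph, link, probe, n_histories = 3L, seed = 13L)
  c_med <- light_speed(med)
  for (h in tr) {
    v <- h$vertices
    # straight flight to the bottom at depth 4 mm
    expect_equal(v$z[nrow(v)], 4, tolerance = 1e-6)
    expect_equal(v$t[nrow(v)], 4 / c_med, tolerance = 1e-6)
    expect_equal(v$w[nrow(v)], exp(-0.05 * 4), tolerance = 1e-12)
  }

  # diffusive medium: weight at every vertex equals exp(-mua * path length)
  ph2 <- desk_phantom()
  tr2 <- trace_history(ph2, centered_link(), probe_geometry(),
                       n_histories = 5L, seed = 17L, max_time = 300)
  for (h in tr2) {
    v <- h$vertices
    if (nrow(v) < 2) next
    path <- cumsum(c(0, sqrt(diff(v$x)^2 + diff(v$y)^2 + diff(v$z)^2)))
    keep <- v$w > 1e-4                 # before any roulette boost
    expect_equal(v$w[keep], exp(-0.01 * path[keep]), tolerance = 1e-10)
    # time accounting along the same path
    expect_equal(v$t, path / light_speed(ph2$medium), tolerance = 1e-6)
  }
})

test_that("fluorescent conversion spawns carry the first-order weight", {
  ph <- desk_phantom()
  tr <- trace_history(ph, centered_link(), probe_geometry(),
                      n_histories = 40L, seed = 23L, max_time = 300,
                      with_delay = TRUE)
  n_spawned <- 0L
  for (h in tr) {
    sp <- h$spawns
    if (nrow(sp) == 0) next
    n_spawned <- n_spawned + nrow(sp)
    # spawn positions lie inside the fluorophore cylinder (centre-in-voxel
    # voxelization allows up to half a voxel diagonal of overshoot)
    rad <- sqrt((sp$y - 7.5)^2 + (sp$z - 4.4)^2)
    expect_true(all(rad <= 1 + 0.25 * sqrt(3) / 2 + 1e-9))
    # spawn weight = upstream survival x mua x crossing length; bounded by
    # mua times the voxel diagonal
    expect_true(all(sp$w <= 0.01 * 0.25 * sqrt(3) + 1e-12))
    expect_true(all(sp$w > 0))
  }
  expect_gt(n_spawned, 0L)
  # trajectories that never cross the fluorophore spawn nothing
  ph0 <- make_phantom(desk_grid(), study_medium(), study_fluor(),
                      cylinder_shape(c(0, 7.5, 4.4), radius = 0, axis = 1L))
  tr0 <- trace_history(ph0, centered_link(), n_histories = 10L, seed = 29L)
  expect_true(all(vapply(tr0, function(h) nrow(h$spawns), 0L) == 0L))
})

test_that("sampled emission delays are exponential with mean tau", {
  ph <- desk_phantom()
  delays <- numeric(0)
  s <- 0L
  while (length(delays) < 3000L && s < 40L) {
    s <- s + 1L
    tr <- trace_history(ph, centered_link(), n_histories = 60L,
                        seed = 100L + s, with_delay = TRUE, max_time = 300)
    delays <- c(delays, unlist(lapply(tr, function(h) h$spawns$delay)))
  }
  expect_gte(length(delays), 1000L)
  se <- sd(delays) / sqrt(length(delays))
  expect_lt(abs(mean(delays) - 900), 3 * se)
})

test_that("single-history sensitivity accumulation matches a hand oracle", {
  # One forced straight-line history through a two-voxel fluorophore: the
  # history-estimator volume must equal the per-crossing Beer-Lambert
  # summand recomputed by hand from the trace.
  grid <- voxel_grid(c(8L, 8L, 8L), 0.5)
  med <- optical_medium(mua = 0.2, mus = 1e-9, g = 0, n = 1.0)
  flu <- study_fluor()
  ph <- make_phantom(grid, med, flu, box_shape(c(2, 2, 1.5), c(2, 2, 0.5)))
  probe <- probe_geometry(fiber_diameter = 1e-9, critical_angle = 1e-7)
  link <- list(sx = 1.75, sy = 1.75, dx = 2.85, dy = 1.75, sr_distance = 1.1)
  tr <- trace_history(ph, link, probe, n_histories = 1L, seed = 7L)[[1]]
  sp <- tr$spawns
  expect_gt(nrow(sp), 0)
  # hand recomputation: straight path down, attenuation exp(-mua z_entry)
  for (i in seq_len(nrow(sp))) {
    seg <- traverse_voxels(c(1.75, 1.75, 0), c(1.75, 1.75, sp$z[i] * 2), grid)
    z_entry <- sp$z[i] - seg$length[nrow(seg)] / 2  # midpoint convention
    expect_equal(sp$w[i],
                 exp(-0.2 * z_entry) * 0.2 * seg$length[nrow(seg)],
                 tolerance = 1e-6)
  }
})

test_that("gate monotonicity, determinism and weight conservation hold", {
  ph <- desk_phantom()
  link <- centered_link()
  vols <- compute_sensitivity(ph, link, gates = c(66, 100, 200),
                              n_histories = 2e4, seed = 41L)
  expect_true(all(vols[[1]] <= vols[[2]]))
  expect_true(all(vols[[2]] <= vols[[3]]))
  expect_true(all(vols[[3]] >= 0))
  # zero gate gives an all-zero volume
  v0 <- compute_sensitivity(ph, link, gates = 0, n_histories = 5000,
                            seed = 43L, max_time = 10)
  expect_true(all(v0 == 0))
  # bitwise-identical reruns for both estimators
  again <- compute_sensitivity(ph, link, gates = c(66, 100, 200),
                               n_histories = 2e4, seed = 41L)
  expect_identical(lapply(vols, as.numeric), lapply(again, as.numeric))
  h1 <- simulate_ftpsf(ph, link, n_histories = 1e4, seed = 47L,
                       max_time = 300, estimator = "history")
  h2 <- simulate_ftpsf(ph, link, n_histories = 1e4, seed = 47L,
                       max_time = 300, estimator = "history")
  expect_identical(h1$value, h2$value)
  # detected weight cannot exceed launched weight
  expect_lte(attr(h1, "detected_weight"), attr(h1, "launched_weight"))
  expect_error(simulate_ftpsf(ph, link, n_histories = 0), "n_histories")
})

test_that("the factorized and per-history estimators agree", {
  # A permissive detector makes analog detection frequent, so the history
  # estimator converges quickly; both estimators then measure the same
  # physical quantity through entirely different computational routes.
  grid <- voxel_grid(c(30L, 30L, 20L), 0.5)
  ph <- make_phantom(grid, study_medium(), study_fluor(),
                     cylinder_shape(c(0, 7.5, 3.0), radius = 1.5, axis = 1L))
  probe <- probe_geometry(fiber_diameter = 3, numerical_aperture = 0.9,
                          critical_angle = 45, sr_offsets = 3)
  link <- list(sx = 5.5, sy = 7.5, dx = 8.5, dy = 7.5, sr_distance = 3)
  sh <- compute_sensitivity(ph, link, probe, gates = 200, n_histories = 2e5,
                            seed = 51L, estimator = "history",
                            nee_split = 1e9)      # pure analog reference
  sp <- compute_sensitivity(ph, link, probe, gates = 200, n_histories = 2e5,
                            seed = 53L, estimator = "pair")
  expect_equal(sum(sh), sum(sp), tolerance = 0.06)
  top <- ph$mask & sp > stats::quantile(sp[ph$mask], 0.7)
  expect_equal(stats::median(sh[top] / sp[top]), 1, tolerance = 0.12)
})

test_that("doubling the histories halves the MC variance of the estimate", {
  ph <- desk_phantom()
  link <- centered_link()
  gate_at <- function(n, s)
    gate_value(simulate_ftpsf(ph, link, n_histories = n, seed = s,
                              max_time = 250), 200)
  v1 <- vapply(1:8, function(s) gate_at(5e3, 200 + 10 * s), 0)
  v4 <- vapply(1:8, function(s) gate_at(2e4, 600 + 10 * s), 0)
  # fourfold histories: sd should drop by about 2 (allow a loose band)
  ratio <- sd(v1) / sd(v4)
  expect_gt(ratio, 1.2)
})
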