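test_that("noiseless separation recovers the generating parameters exactly", {
  med <- study_medium(); flu <- study_fluor()
  f <- fpdf_value(med, flu, v_strategy2)
  s <- separate_voxel(f, v_strategy2, med, flu$gamma,
                      separation_params(omega = 0))
  expect_equal(s$muaf, 0.01, tolerance = 1e-9)
  expect_equal(s$tau, 900, tolerance = 1e-9)
  expect_true(s$valid)
})

test_that("noiseless recovery is exact across the physical parameter range", {
  med <- study_medium()
  p0 <- separation_params(omega = 0, tau_max = 1e5)
  set.seed(3)
  for (k in 1:40) {
    muaf <- runif(1, 1e-4, 0.1)
    tau <- runif(1, 1, 5000)
    gam <- runif(1, 0.05, 1)
    flu <- fluorophore_props(muaf, gam, tau)
    v <- v_strategy2
    f <- fpdf_value(med, flu, v)
    s <- separate_voxel(f, v, med, gam, p0)
    expect_equal(s$muaf, muaf, tolerance = 1e-8)
    expect_equal(s$tau, tau, tolerance = 1e-8)
  }
})

test_that("degenerate voxels are flagged, duplicate velocities rejected", {
  med <- study_medium()
  s <- separate_voxel(c(0, 0, 0), v_strategy2, med, 0.2)
  expect_equal(s$muaf, 0)
  expect_true(is.na(s$tau))
  expect_false(s$valid)
  expect_error(separate_voxel(c(1, 2, 3) * 1e-3, c(0.01, 0.01, 0.02), med, 0.2),
               "singular")
})

test_that("damped solution matches the normal-equations oracle", {
  med <- study_medium(); flu <- study_fluor()
  fdc <- 4 * diffusion_coefficient(med) * light_speed(med)
  params <- separation_params(omega = 1e-3)
  set.seed(11)
  for (k in 1:1000) {
    f0 <- fpdf_value(med, flu, v_strategy2)
    f <- f0 * (1 + rnorm(3, 0, 0.01))          # ~1% perturbations
    s <- separate_voxel(f, v_strategy2, med, flu$gamma, params)
    # independent oracle: damped normal equations of the column-equilibrated
    # system, (As'As + w^2 I) xs = As'b with As = A D^-1, x = D^-1 xs
    A <- cbind(fdc * flu$gamma, -f * v_strategy2^2)
    b <- fdc * f
    D <- sqrt(colSums(A^2))
    As <- sweep(A, 2, D, "/")
    xs <- solve(crossprod(As) + params$omega^2 * diag(2), crossprod(As, b))
    x <- xs / D
    expect_equal(s$muaf, x[1], tolerance = 1e-8)
    expect_equal(s$tau, x[2], tolerance = 1e-8)
  }
})

test_that("volume separation is a voxelwise round trip with validity masking", {
  med <- study_medium()
  shp <- c(6L, 5L, 4L)
  set.seed(5)
  muaf_map <- array(runif(prod(shp), 0.002, 0.05), shp)
  tau_map <- array(runif(prod(shp), 200, 2500), shp)
  gam <- 0.2
  fdc <- 4 * diffusion_coefficient(med) * light_speed(med)
  vols <- lapply(v_strategy2, function(v)
    fdc * gam * muaf_map / (v^2 * tau_map + fdc))
  maps <- separate_volume(vols, v_strategy2, med, gam,
                          separation_params(omega = 0, f_threshold = 0))
  expect_true(all(maps$valid_mask))
  expect_equal(maps$muaf_map, muaf_map, tolerance = 1e-8)
  expect_equal(maps$tau_map, tau_map, tolerance = 1e-8)

  # zero a region: flagged invalid, zero-filled
  vols0 <- vols
  for (m in 1:3) vols0[[m]][1:2, , ] <- 0
  maps0 <- separate_volume(vols0, v_strategy2, med, gam,
                           separation_params(omega = 0, f_threshold = 0.01))
  expect_false(any(maps0$valid_mask[1:2, , ]))
  expect_true(all(maps0$muaf_map[1:2, , ] == 0))
  expect_true(all(is.na(maps0$tau_map[1:2, , ])))
  expect_true(all(maps0$valid_mask[3:6, , ]))

  # empty grid
  e <- separate_volume(list(array(0, c(0, 2, 2)), array(0, c(0, 2, 2)),
                            array(0, c(0, 2, 2))), v_strategy2, med, gam)
  expect_identical(dim(e$muaf_map), c(0L, 2L, 2L))
  expect_error(
    separate_volume(list(vols[[1]], vols[[2]], array(0, c(2, 2, 2))),
                    v_strategy2, med, gam), "share one grid")
})

test_that("volume and voxel solvers agree voxel by voxel under damping", {
  med <- study_medium(); flu <- study_fluor()
  params <- separation_params(omega = 5e-3, f_threshold = 0)
  set.seed(9)
  shp <- c(4L, 3L, 2L)
  vols <- lapply(v_strategy2, function(v) {
    f0 <- fpdf_value(med, flu, v)
    array(f0 * (1 + rnorm(prod(shp), 0, 0.05)), shp)
  })
  maps <- separate_volume(vols, v_strategy2, med, flu$gamma, params)
  for (i in seq_len(prod(shp))) {
    f <- c(vols[[1]][i], vols[[2]][i], vols[[3]][i])
    s <- separate_voxel(f, v_strategy2, med, flu$gamma, params)
    expect_equal(maps$muaf_map[i],
                 if (maps$valid_mask[i]) s$muaf else 0, tolerance = 1e-8)
    if (maps$valid_mask[i]) expect_equal(maps$tau_map[i], s$tau,
                                         tolerance = 1e-8)
  }
})
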