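toy_system <- function(W, g) {
  # minimal linear_system for solver tests
  structure(list(W = W, g = g,
                 grid = voxel_grid(c(ncol(W), 1L, 1L), 1),
                 meta = NULL, entry = NULL),
            class = "linear_system")
}

test_that("a single relaxed Kaczmarz sweep has the closed-form behaviour", {
  sys <- toy_system(matrix(2, 1, 1), 4)
  expect_equal(art_sweep(sys, 0, lam = 1), 2)          # exact one-row solve
  f <- c(1, 2)
  sys2 <- toy_system(matrix(c(1, 0, 0, 1), 2, 2), c(1, 2))
  expect_equal(art_sweep(sys2, f, 0.9), f)             # fixed point
  # residual never increases on a consistent system
  set.seed(2)
  for (k in 1:10) {
    W <- matrix(rnorm(12), 4, 3)
    x <- rnorm(3)
    g <- as.numeric(W %*% x)
    f0 <- rnorm(3)
    for (lam in c(0.3, 0.9, 1)) {
      f1 <- art_sweep(toy_system(W, g), f0, lam)
      expect_lte(sqrt(sum((W %*% f1 - g)^2)),
                 sqrt(sum((W %*% f0 - g)^2)) + 1e-12)
    }
  }
  # zero-norm rows are skipped
  sysz <- toy_system(rbind(c(0, 0), c(1, 0)), c(5, 3))
  expect_equal(art_sweep(sysz, c(0, 0), 1), c(3, 0))
})

test_that("shrinkage is the soft-threshold operator and non-expansive", {
  expect_equal(shrink(c(1, 0.0005, -1), 0.001, 0.9),
               c(0.9991, 0, -0.9991))
  v <- c(0.2, -0.5, 0.8)
  expect_equal(shrink(v, 0, 0.9), v)                    # identity at alpha = 0
  expect_equal(shrink(c(1e-4, -8e-4), 0.001, 0.9), c(0, 0))
  set.seed(4)
  for (k in 1:50) {
    a <- rnorm(10); b <- rnorm(10)
    expect_lte(sqrt(sum((shrink(a, 0.05, 0.9) - shrink(b, 0.05, 0.9))^2)),
               sqrt(sum((a - b)^2)) + 1e-12)
  }
})

test_that("momentum recursion and cycle fixed points are correct", {
  # t^(2) = (1 + sqrt(5)) / 2 from t^(1) = 1
  t1 <- 1
  t2 <- (1 + sqrt(1 + 4 * t1^2)) / 2
  expect_equal(t2, (1 + sqrt(5)) / 2)
  # zero data with positive shrinkage stays at zero
  sys <- toy_system(matrix(rnorm(6), 2, 3), c(0, 0))
  sys$g <- c(0, 0)
  out <- fist_cycle(sys, rep(0, 3), recon_params(alpha = 0.01, s_artfist = 20))
  expect_equal(out, rep(0, 3))
  # overdetermined consistent system solved to high accuracy
  set.seed(6)
  W <- matrix(rnorm(6), 3, 2)
  x <- c(0.7, -0.3)
  sys3 <- toy_system(W, as.numeric(W %*% x))
  out <- fist_cycle(sys3, c(0, 0),
                    recon_params(lam = 1, alpha = 0, s_artfist = 100))
  expect_equal(out, x, tolerance = 1e-6)
})

test_that("TV norm descends under the scheduled gradient step", {
  cst <- array(2.5, c(4, 4, 3))
  expect_equal(tv_step(cst, 0.005), cst)                # zero gradient
  set.seed(8)
  noisy <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  stepped <- tv_step(noisy, 0.005)
  expect_lt(tv_norm(stepped), tv_norm(noisy))
  # step-size schedule: beta_k = 0.005 * 0.997^k
  p <- recon_params()
  expect_equal(p$beta0 * p$beta_decay^10, 0.005 * 0.997^10)
})

test_that("the full solver handles degenerate and small synthetic systems", {
  # zero data -> zero volume
  shp <- c(4L, 4L, 2L)
  W <- matrix(abs(rnorm(5 * prod(shp))), 5, prod(shp))
  sys <- structure(list(W = W, g = rep(0, 5), grid = voxel_grid(shp, 1),
                        meta = NULL, entry = NULL), class = "linear_system")
  rec <- reconstruct(sys, recon_params(max_outer = 3))
  expect_true(all(rec$volume == 0))

  # plain ART-with-momentum degeneration solves a consistent system
  set.seed(10)
  shp <- c(3L, 2L, 2L)
  I <- prod(shp)
  W2 <- matrix(rnorm(I * I), I, I)
  x <- runif(I)
  sys2 <- structure(list(W = W2, g = as.numeric(W2 %*% x),
                         grid = voxel_grid(shp, 1), meta = NULL,
                         entry = NULL), class = "linear_system")
  rec2 <- reconstruct(sys2, recon_params(lam = 1, alpha = 0, s_tv = 0L,
                                         s_artfist = 200L, tol = 0,
                                         max_outer = 10L, nonneg = FALSE))
  expect_equal(as.numeric(rec2$volume), x, tolerance = 1e-6)

  # determinism: bitwise identical reruns
  rec3 <- reconstruct(sys2, recon_params(lam = 1, alpha = 0, s_tv = 0L,
                                         s_artfist = 200L, tol = 0,
                                         max_outer = 10L, nonneg = FALSE))
  expect_identical(rec2$volume, rec3$volume)
})

test_that("piecewise-constant and sparse synthetic phantoms are recovered", {
  # piecewise-constant plateau probed by 60 localized sensitivity-like
  # kernel rows (a raster of Gaussian blobs, as a scan produces)
  set.seed(12)
  shp <- c(16L, 16L, 4L)
  I <- prod(shp)
  truth <- array(0, shp)
  truth[5:12, 5:12, 2:3] <- 2e-3
  centers <- expand.grid(x = seq(2, 15, length.out = 6),
                         y = seq(2, 15, length.out = 5), z = c(2, 3))
  idx <- expand.grid(x = 1:16, y = 1:16, z = 1:4)
  W <- matrix(0, nrow(centers), I)
  for (j in seq_len(nrow(centers)))
    W[j, ] <- exp(-((idx$x - centers$x[j])^2 + (idx$y - centers$y[j])^2) /
                    (2 * 2^2) - (idx$z - centers$z[j])^2 / (2 * 1.5^2))
  g <- as.numeric(W %*% as.numeric(truth))
  sys <- structure(list(W = W, g = g, grid = voxel_grid(shp, 1), meta = NULL,
                        entry = NULL), class = "linear_system")
  rec <- reconstruct(sys, recon_params(alpha = 1e-3, s_artfist = 150L,
                                       s_tv = 3L, max_outer = 30L,
                                       f_scale = 2e-3))
  plateau <- rec$volume[5:12, 5:12, 2:3]
  expect_lt(abs(mean(plateau) - 2e-3) / 2e-3, 0.15)

  # sparse hot voxels from 30 random projections: support recovered by the
  # shrinkage stage with few spurious voxels
  shp2 <- c(40L, 40L, 1L)
  I2 <- prod(shp2)
  truth2 <- numeric(I2)
  hot <- c(220, 800, 1205)
  truth2[hot] <- 1
  set.seed(13)
  W2 <- matrix(rnorm(30 * I2), 30, I2)
  sys2 <- structure(list(W = W2, g = as.numeric(W2 %*% truth2),
                         grid = voxel_grid(shp2, 1), meta = NULL,
                         entry = NULL), class = "linear_system")
  rec2 <- reconstruct(sys2, recon_params(alpha = 5e-3, s_artfist = 100L,
                                         s_tv = 0L, max_outer = 15L))
  above <- which(as.numeric(rec2$volume) > max(rec2$volume) / 2)
  expect_true(all(hot %in% above))
  expect_lte(length(setdiff(above, hot)), 2L)
})
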