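#' Parameters of the hybrid ART-FIST-TV solver
#'
#' @param lam Relaxation of the Kaczmarz (ART) row updates, in `(0, 1]`.
#' @param alpha Shrinkage regularization weight, `>= 0`; the soft threshold
#'   applied after each sweep is `alpha * lam`.
#' @param s_artfist Inner ART-FIST iterations per outer cycle.
#' @param s_tv TV gradient-descent iterations per outer cycle (`0` disables
#'   the TV stage).
#' @param beta0 Initial TV step size.
#' @param beta_decay Per-TV-iteration multiplier of the step size.
#' @param tol Outer-cycle stop threshold on the relative L2 change.
#' @param max_outer Cap on outer cycles.
#' @param nonneg Clip the volume at zero after each outer cycle (the FPDF is
#'   physically nonnegative).
#' @param f_scale Image normalization (units of the volume): the system is
#'   solved for `f / f_scale` and rescaled afterwards. The shrinkage
#'   threshold `alpha * lam` and the TV step act on order-one images, so
#'   `f_scale` should be the nominal magnitude of the expected solution
#'   (for an FPDF reconstruction, the model FPDF value of the entry).
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(lam = 0.9, alpha = 0.001, s_artfist = 50L,
                         s_tv = 3L, beta0 = 0.005, beta_decay = 0.997,
                         tol = 1e-4, max_outer = 30L, nonneg = TRUE,
                         f_scale = 1) {
  stopifnot(lam > 0, lam <= 1, alpha >= 0, s_artfist >= 1L, s_tv >= 0L,
            beta0 > 0, beta_decay > 0, beta_decay <= 1, tol >= 0,
            max_outer >= 1L, f_scale > 0)
  structure(list(lam = lam, alpha = alpha, s_artfist = as.integer(s_artfist),
                 s_tv = as.integer(s_tv), beta0 = beta0,
                 beta_decay = beta_decay, tol = tol,
                 max_outer = as.integer(max_outer), nonneg = isTRUE(nonneg),
                 f_scale = f_scale),
            class = "recon_params")
}

# Internal transposed form of a system for cache-friendly sweeps.
system_t <- function(system) {
  Wt <- t(system$W)
  list(Wt = Wt, g = system$g, row_norms2 = colSums(Wt^2))
}

#' One relaxed Kaczmarz sweep
#'
#' Sequential ART row updates `f <- f + lam (g_j - <w_j, f>) / ||w_j||^2 w_j`
#' over all rows once, in stored (zigzag scan) order; zero-norm rows are
#' skipped. On a consistent system the residual norm never increases for
#' `0 < lam <= 1`.
#'
#' @param system A `linear_system` (or a list with `W`, `g`).
#' @param f Current volume vector (length `ncol(W)`).
#' @param lam Relaxation in `(0, 1]`.
#' @return The updated vector.
#' @export
art_sweep <- function(system, f, lam = 0.9) {
  st <- if (!is.null(system$Wt)) system else system_t(system)
  art_sweep_t(st$Wt, st$g, as.numeric(f), lam, st$row_norms2)
}

#' Soft-thresholding shrinkage
#'
#' `sign(f) * max(|f| - alpha * lam, 0)`, the proximal operator of the L1
#' penalty used between ART sweeps. Non-expansive; the identity at
#' `alpha = 0`.
#'
#' @param f Numeric vector/array.
#' @param alpha Regularization weight.
#' @param lam ART relaxation (the threshold is their product).
#' @return Shrunk values, same shape.
#' @export
shrink <- function(f, alpha, lam = 0.9) {
  thr <- alpha * lam
  sign(f) * pmax(abs(f) - thr, 0)
}

#' One cycle of ART-FIST iterations
#'
#' `s_artfist` iterations of `f^(s) = Shrink(ART(y^(s)))` with the momentum
#' recursion `t^(s+1) = (1 + sqrt(1 + 4 t^(s)^2)) / 2` and extrapolation
#' `y^(s+1) = f^(s) + (t^(s)-1)/t^(s+1) (f^(s) - f^(s-1))`, starting from
#' `y^(1) = f0`, `t^(1) = 1`. Returns the final extrapolated iterate.
#'
#' @param system A `linear_system`.
#' @param f0 Starting volume vector.
#' @param params A [recon_params()].
#' @return The vector after the cycle.
#' @export
fist_cycle <- function(system, f0, params = recon_params()) {
  st <- if (!is.null(system$Wt)) system else system_t(system)
  y <- as.numeric(f0)
  f_prev <- as.numeric(f0)
  t_s <- 1
  res_prev <- Inf
  for (s in seq_len(params$s_artfist)) {
    f_s <- shrink(art_sweep(st, y, params$lam), params$alpha, params$lam)
    # adaptive (function-value) restart: a Kaczmarz sweep is not a 1/L
    # gradient step, so the momentum recursion is only conditionally stable.
    # Whenever the data residual of the new iterate grows, the momentum is
    # reset and the extrapolation skipped; with a monotone operator this
    # provably prevents the oscillatory divergence while keeping the
    # acceleration where it helps.
    res_s <- sqrt(sum((as.numeric(crossprod(st$Wt, f_s)) - st$g)^2))
    if (res_s > res_prev) {
      t_s <- 1
      y <- f_s
    } else {
      t_next <- (1 + sqrt(1 + 4 * t_s^2)) / 2
      y <- f_s + (t_s - 1) / t_next * (f_s - f_prev)
      t_s <- t_next
    }
    res_prev <- res_s
    f_prev <- f_s
  }
  y
}

#' Smoothed isotropic total-variation norm and one descent step
#'
#' `tv_norm` evaluates the epsilon-smoothed isotropic 3-D TV norm
#' `sum sqrt(dx^2 + dy^2 + dz^2 + eps)` with one-sided forward differences
#' and reflective boundaries. `tv_step` takes one steepest-descent step
#' `f - beta * grad` on it.
#'
#' @param f 3-D numeric array.
#' @param beta Step size, `> 0`.
#' @param eps Smoothing constant in the gradient denominator.
#' @return `tv_norm`: scalar. `tv_step`: array of the same shape.
#' @export
tv_norm <- function(f, eps = 1e-8) {
  d <- dim(f)
  ix <- if (d[1] > 1) c(2:d[1], d[1]) else 1
  iy <- if (d[2] > 1) c(2:d[2], d[2]) else 1
  iz <- if (d[3] > 1) c(2:d[3], d[3]) else 1
  dx <- f[ix, , , drop = FALSE] - f
  dy <- f[, iy, , drop = FALSE] - f
  dz <- f[, , iz, drop = FALSE] - f
  sum(sqrt(dx^2 + dy^2 + dz^2 + eps))
}

#' @rdname tv_norm
#' @export
tv_step <- function(f, beta, eps = 1e-8) {
  stopifnot(beta > 0, length(dim(f)) == 3L)
  d <- dim(f)
  ix <- if (d[1] > 1) c(2:d[1], d[1]) else 1
  iy <- if (d[2] > 1) c(2:d[2], d[2]) else 1
  iz <- if (d[3] > 1) c(2:d[3], d[3]) else 1
  ixm <- if (d[1] > 1) c(1, 1:(d[1] - 1)) else 1
  iym <- if (d[2] > 1) c(1, 1:(d[2] - 1)) else 1
  izm <- if (d[3] > 1) c(1, 1:(d[3] - 1)) else 1
  dx <- f[ix, , , drop = FALSE] - f
  dy <- f[, iy, , drop = FALSE] - f
  dz <- f[, , iz, drop = FALSE] - f
  den <- sqrt(dx^2 + dy^2 + dz^2 + eps)
  # d/df_i of sum_k sqrt(.)_k: the term at i contributes -(dx+dy+dz)/den_i,
  # the backward neighbours along each axis contribute +d./den_neighbour.
  grad <- -(dx + dy + dz) / den +
    (f - f[ixm, , , drop = FALSE]) / den[ixm, , , drop = FALSE] +
    (f - f[, iym, , drop = FALSE]) / den[, iym, , drop = FALSE] +
    (f - f[, , izm, drop = FALSE]) / den[, , izm, drop = FALSE]
  f - beta * grad
}

#' Reconstruct an FPDF volume with ART-FIST-TV
#'
#' Alternates an inner cycle of relaxed Kaczmarz sweeps with shrinkage and
#' FISTA momentum and an inner cycle of TV gradient descent, until the
#' relative L2 change between outer iterates drops below `tol` or `max_outer`
#' cycles are done. The TV step size starts at `beta0` and is multiplied by
#' `beta_decay` after every TV iteration, across outer cycles. The result is
#' deterministic for fixed inputs. Residual growth over five consecutive
#' outer cycles is treated as divergence and raises an error.
#'
#' @param system A [assemble()]d `linear_system`.
#' @param params A [recon_params()].
#' @param f0 Starting volume (default zeros).
#' @return An object of class `fpdf_recon`: list with the volume array
#'   `volume`, the iteration `log` (data.frame: outer, residual, tv,
#'   rel_change) and `params`.
#' @export
reconstruct <- function(system, params = recon_params(), f0 = NULL) {
  stopifnot(inherits(system, "linear_system"))
  st <- system_t(system)
  st$grid <- system$grid
  fs <- if (is.null(params$f_scale)) 1 else params$f_scale
  st$g <- st$g / fs
  shp <- system$grid$shape
  I <- prod(shp)
  f <- if (is.null(f0)) numeric(I) else as.numeric(f0) / fs
  stopifnot(length(f) == I)
  beta <- params$beta0
  log_rows <- vector("list", params$max_outer)
  res_prev <- Inf
  res_best <- Inf
  grow <- 0L
  for (outer in seq_len(params$max_outer)) {
    f_old <- f
    f <- fist_cycle(st, f, params)
    if (params$s_tv > 0L) {
      vol <- array(f, dim = shp)
      for (k in seq_len(params$s_tv)) {
        vol <- tv_step(vol, beta)
        beta <- beta * params$beta_decay
      }
      f <- as.numeric(vol)
    }
    if (params$nonneg) f <- pmax(f, 0)
    res <- sqrt(sum((as.numeric(crossprod(st$Wt, f)) - st$g)^2))
    denom <- sqrt(sum(f_old^2))
    rel <- if (denom > 0) sqrt(sum((f - f_old)^2)) / denom else Inf
    log_rows[[outer]] <- data.frame(outer = outer, residual = res,
                                    tv = tv_norm(array(f, dim = shp)),
                                    rel_change = rel)
    # divergence: sustained, substantial residual growth (the TV stage makes
    # the data residual oscillate slightly near the plateau, which is benign)
    grow <- if (res > res_prev * 1.001) grow + 1L else 0L
    res_best <- min(res_best, res)
    if (grow >= 5L && res > 2 * res_best)
      stop("reconstruct: residual grew over 5 consecutive outer cycles (divergence)")
    res_prev <- res
    if (is.finite(rel) && rel < params$tol) break
  }
  structure(list(volume = array(f * fs, dim = shp),
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]),
                 params = params),
            class = "fpdf_recon")
}

#' @export
print.fpdf_recon <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<fpdf_recon> %d outer cycles, final residual %.4g, max f %.4g\n",
              n, x$log$residual[n], max(x$volume)))
  invisible(x)
}
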