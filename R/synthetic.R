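#' Parameters of the synthetic response generator
#'
#' Controls the forward model used to manufacture noisy measured-like
#' fluorescence temporal responses from modelled temporal point spread
#' functions: `FTR = C * FTPSF (x) IRF(t - t_shift) + shot noise`, with a
#' Gaussian instrument response, a stochastic shift of the time origin and
#' Poisson counting noise (TCSPC physics).
#'
#' @param coupling Coupling factor C, `> 0`.
#' @param irf_fwhm IRF full width at half maximum (ps), `> 0`.
#' @param irf_t0 IRF peak position on the time grid (ps).
#' @param t_shift Time-origin shift (ps): a number, or `NA` to draw uniformly
#'   from `shift_window`.
#' @param shift_window Half-width (ps) of the uniform stochastic-shift window
#'   used when `t_shift` is `NA`.
#' @param peak_counts Target counts at the response maximum (sets the shot
#'   noise level; peak SNR is about `sqrt(peak_counts)`).
#' @return An object of class `synthetic_ftr_params`.
#' @export
synthetic_ftr_params <- function(coupling = 1, irf_fwhm = 50, irf_t0 = 150,
                                 t_shift = NA_real_, shift_window = 20,
                                 peak_counts = 1e4) {
  stopifnot(coupling > 0, irf_fwhm > 0, peak_counts >= 1, shift_window >= 0)
  structure(list(coupling = coupling, irf_fwhm = irf_fwhm, irf_t0 = irf_t0,
                 t_shift = t_shift, shift_window = shift_window,
                 peak_counts = peak_counts),
            class = "synthetic_ftr_params")
}

#' Synthetic Gaussian instrument response function
#'
#' A unit-area Gaussian pulse of the given FWHM centred at `t0` on a uniform
#' time grid (area means `sum(values) * bin_width`). The zero-width limit
#' degenerates to a single-bin impulse.
#'
#' @param fwhm Full width at half maximum (ps), `> 0` (very small values give
#'   an impulse).
#' @param t0 Centre (ps).
#' @param bin_width Bin width (ps).
#' @param max_time Grid length (ps).
#' @return A [time_curve()] of kind `"IRF"`.
#' @export
make_irf <- function(fwhm = 50, t0 = 150, bin_width = 2, max_time = 1000) {
  stopifnot(fwhm > 0, bin_width > 0, max_time > bin_width)
  edges <- seq(0, by = bin_width, length.out = ceiling(max_time / bin_width) + 1L)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (sigma < bin_width / 20) {
    v <- numeric(length(centers))
    v[which.min(abs(centers - t0))] <- 1
  } else {
    v <- exp(-(centers - t0)^2 / (2 * sigma^2))
  }
  v <- v / (sum(v) * bin_width)
  time_curve(edges, v, kind = "IRF")
}

#' Synthesize a noisy measured-like response
#'
#' Forward model of the measurement chain: the modelled FTPSF is scaled by
#' the coupling factor, convolved with the IRF displaced by the (possibly
#' stochastic) time-origin shift, rescaled so its maximum is `peak_counts`,
#' and Poisson noise is drawn per bin. Deterministic for a fixed seed.
#'
#' @param ftpsf A [time_curve()] (kind FTPSF) on the standard grid.
#' @param irf A [time_curve()] (kind IRF) on the same grid.
#' @param params A [synthetic_ftr_params()].
#' @param seed Integer seed.
#' @param noise Set `FALSE` to skip the Poisson stage (and the peak-counts
#'   rescaling is still applied).
#' @return A [time_curve()] of kind `"FTR"` with attributes `t_shift_ps` and
#'   `scale` (counts per model unit).
#' @export
synthesize_ftr <- function(ftpsf, irf, params = synthetic_ftr_params(),
                           seed = 1L, noise = TRUE) {
  stopifnot(inherits(ftpsf, "time_curve"), inherits(irf, "time_curve"),
            inherits(params, "synthetic_ftr_params"))
  if (!same_grid(ftpsf, irf))
    stop("synthesize_ftr: FTPSF and IRF must share one time grid")
  set.seed(as.integer(seed))
  shift <- params$t_shift
  if (is.na(shift)) shift <- stats::runif(1, -1, 1) * params$shift_window
  bw <- curve_bin_width(ftpsf)
  irf_shifted <- align_time_origin(irf, shift)
  k <- irf_shifted$value
  u <- params$coupling * ftpsf$value
  n <- length(u)
  conv <- stats::convolve(u, rev(k), type = "open")[seq_len(n)] * bw
  conv <- pmax(conv, 0)
  pk <- max(conv)
  scale <- if (pk > 0) params$peak_counts / pk else 1
  lam <- conv * scale
  v <- if (noise) stats::rpois(n, lam) else lam
  out <- curve_with_values(ftpsf, v, kind = "FTR")
  attr(out, "t_shift_ps") <- attr(irf_shifted, "shift_ps")
  attr(out, "scale") <- scale
  out
}

#' Generate a self-contained synthetic fixture bundle
#'
#' Runs the forward chain for a (typically reduced) phantom and scan: the
#' phantom volume, per-link modelled FTPSFs, synthetic noisy FTRs, the IRF,
#' middle-row sensitivity volumes for every (distance, gate) pair of the
#' strategy, and ground-truth FPDF volumes at the strategy velocities. All
#' files are written under `dir` together with a JSON manifest of every
#' parameter and seed, so the bundle can be reproduced bit for bit.
#'
#' @param dir Output directory (created if needed).
#' @param phantom A [make_phantom()] object.
#' @param pattern A [scan_pattern()].
#' @param probe A [probe_geometry()].
#' @param strategy A strategy from [build_strategy1()]/[build_strategy2()].
#' @param n_histories MC histories per link.
#' @param seed Master seed; per-link seeds are derived deterministically.
#' @param ftr_params A [synthetic_ftr_params()].
#' @param bin_width,max_time Time grid of the curves (ps).
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
make_fixture <- function(dir, phantom, pattern, probe = probe_geometry(),
                         strategy = build_strategy2(), n_histories = 1e5,
                         seed = 1L, ftr_params = synthetic_ftr_params(),
                         bin_width = 2, max_time = 400) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  links <- scan_links(pattern, probe)
  irf <- make_irf(ftr_params$irf_fwhm, ftr_params$irf_t0, bin_width, max_time)
  write_time_curve(irf, file.path(dir, "irf.tsv"))
  write_volume(phantom$muaf_map, phantom$grid, file.path(dir, "phantom_muaf.nii"))

  ftr_files <- character(nrow(links))
  ftpsf_files <- character(nrow(links))
  for (j in seq_len(nrow(links))) {
    s_j <- seed + j
    ftpsf <- simulate_ftpsf(phantom, links[j, ], probe, n_histories,
                            seed = s_j, bin_width = bin_width,
                            max_time = max_time)
    ftr <- synthesize_ftr(ftpsf, irf, ftr_params, seed = s_j)
    ftpsf_files[j] <- sprintf("ftpsf_%03d.tsv", j)
    ftr_files[j] <- sprintf("ftr_%03d.tsv", j)
    write_time_curve(ftpsf, file.path(dir, ftpsf_files[j]))
    write_time_curve(ftr, file.path(dir, ftr_files[j]))
  }

  pairs <- unique(strategy_pairs(strategy)[c("sr_distance", "gate")])
  mid_row <- (pattern$n_rows + 1L) %/% 2L
  mid <- links[links$row == mid_row, ]
  sens_files <- character(0)
  for (p in seq_len(nrow(pairs))) {
    sel <- mid[abs(mid$sr_distance - pairs$sr_distance[p]) < 1e-9, ]
    for (q in seq_len(nrow(sel))) {
      s_j <- seed + 10000L + 100L * p + q
      vol <- compute_sensitivity(phantom, sel[q, ], probe,
                                 gates = pairs$gate[p],
                                 n_histories = n_histories, seed = s_j)
      fn <- sprintf("sens_R%g_t%g_c%02d.nii", pairs$sr_distance[p],
                    pairs$gate[p], sel$col[q])
      write_volume(as.array(vol), phantom$grid, file.path(dir, fn))
      sens_files <- c(sens_files, fn)
    }
  }

  vels <- vapply(strategy$entries, `[[`, 0, "velocity")
  truth_files <- character(length(vels))
  for (m in seq_along(vels)) {
    ftruth <- fpdf_truth(phantom, vels[m])
    truth_files[m] <- sprintf("fpdf_truth_%d.nii", m)
    write_volume(ftruth, phantom$grid, file.path(dir, truth_files[m]))
  }

  manifest <- list(
    seed = seed, n_histories = n_histories, bin_width = bin_width,
    max_time = max_time, n_links = nrow(links),
    grid = phantom$grid[c("shape", "voxel_size", "origin")],
    medium = unclass(phantom$medium), fluor = unclass(phantom$fluor),
    shape = phantom$shape,
    pattern = unclass(pattern), probe = unclass(probe),
    strategy = strategy$kind, velocities = vels,
    ftr_params = unclass(ftr_params),
    files = list(irf = "irf.tsv", ftpsf = ftpsf_files, ftr = ftr_files,
                 sensitivity = sens_files, fpdf_truth = truth_files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Ground-truth FPDF volume of a phantom
#'
#' Evaluates the closed-form FPDF voxelwise from the phantom's absorption and
#' lifetime maps at one average migration velocity (zero outside the
#' fluorophore mask).
#'
#' @param phantom A [make_phantom()] object.
#' @param v Average migration velocity (mm/ps).
#' @return 3-D array of FPDF values (mm^-1).
#' @export
fpdf_truth <- function(phantom, v) {
  stopifnot(inherits(phantom, "phantom"))
  fdc <- 4 * diffusion_coefficient(phantom$medium) *
    light_speed(phantom$medium)
  out <- array(0, dim = phantom$grid$shape)
  m <- phantom$mask
  out[m] <- fdc * phantom$fluor$gamma * phantom$muaf_map[m] /
    (v^2 * phantom$tau_map[m] + fdc)
  out
}
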