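# Internal: flatten probe + link into the list the C++ engine expects.
# sigma_frac: the truncated-Gaussian launch std as a fraction of the critical
# angle (default 1/2, i.e. the cone edge sits at 2 sigma).
probe_link_spec <- function(probe, link, sigma_frac = 0.5) {
  link <- as_link(link)
  theta_cr <- probe$critical_angle * pi / 180
  list(sx = link$sx, sy = link$sy, dx = link$dx, dy = link$dy,
       fiber_radius = probe$fiber_diameter / 2,
       theta_cr = theta_cr, sigma_launch = sigma_frac * theta_cr)
}

mask_int <- function(phantom) as.integer(phantom$mask)

#' Simulate a fluorescence temporal point spread function
#'
#' Runs the time-resolved fluorescence Monte Carlo engine for one
#' source-detector link and returns the detected fluorescence weight per
#' arrival-time bin. Arrival time includes an exponential emission delay
#' with mean `tau` and the detected weight carries the quantum yield;
#' detection means crossing the detector disk within the in-medium
#' acceptance cone (with Fresnel transmission). Results are normalized per
#' launched history and are bitwise reproducible for a fixed seed.
#'
#' Two estimators are available. `"pair"` (default) exploits the convolution
#' structure of the fluorescence signal: the excitation fluence from the
#' source and, by reciprocity, the detection probability field of the
#' detector are tallied as time-resolved track lengths over the fluorophore
#' voxels in two independent runs of `n_histories` each, then combined by
#' temporal convolution - every history contributes, so the estimator has no
#' rare-event variance. `"history"` follows the per-history realization:
#' fluorescent photons are spawned at each fluorophore-voxel crossing of the
#' excitation trajectory and detection is scored by a hybrid of analytic
#' next-event estimates (final legs longer than one transport split length)
#' and analog detection (shorter legs). The two agree in expectation; the
#' history estimator carries far more variance for sub-millimetre detectors
#' and is retained for validation and cross-checking.
#'
#' @param phantom A [make_phantom()] object.
#' @param link One source-detector link (a row of [scan_links()] or a list
#'   with `sx`, `sy`, `dx`, `dy`).
#' @param probe A [probe_geometry()].
#' @param n_histories Photon history budget per link, `>= 1`. The pair
#'   estimator spends half on the source run and half on the detector run;
#'   the history estimator spends all of it on excitation histories.
#' @param seed Integer RNG seed (the pair estimator derives the adjoint-run
#'   seed from it).
#' @param bin_width Histogram bin width (ps).
#' @param max_time Maximum tracked time (ps); photons beyond it are dropped.
#' @param estimator `"pair"` or `"history"` (see Details).
#' @param walk_thinning History estimator only: probability of following the
#'   scattered random walk of a spawned fluorescent photon
#'   (weight-compensated, unbiased; the direct emission-vertex estimate is
#'   always scored). Values below 1 trade variance for speed.
#' @param nee_split History estimator only: split distance (mm) between
#'   analytic next-event scoring (final legs at least this long) and analog
#'   detection (shorter legs). Very large values give pure analog detection.
#' @return A [time_curve()] of kind `"FTPSF"` with attribute `seed` (and,
#'   for the history estimator, `n_detected`, `launched_weight`,
#'   `detected_weight`).
#' @export
simulate_ftpsf <- function(phantom, link, probe = probe_geometry(),
                           n_histories, seed = 1L, bin_width = 2,
                           max_time = 1000,
                           estimator = c("pair", "history"),
                           walk_thinning = 1, nee_split = 1) {
  stopifnot(inherits(phantom, "phantom"))
  estimator <- match.arg(estimator)
  if (n_histories < 1) stop("simulate_ftpsf: n_histories must be >= 1")
  if (estimator == "pair") {
    nh <- ceiling(n_histories / 2)
    fwd <- deposit_field(phantom, link, probe, nh, seed,
                         bin_width, max_time, adjoint = FALSE)
    adj <- deposit_field(phantom, link, probe, nh, seed + 1L,
                         bin_width, max_time, adjoint = TRUE)
    res <- pair_combine(phantom, fwd, adj, gates = numeric(0),
                        bin_width = bin_width, mode = 1L)
    nb <- length(res$hist)
    tc <- time_curve(seq(0, by = bin_width, length.out = nb + 1L),
                     res$hist, kind = "FTPSF")
    attr(tc, "seed") <- as.integer(seed)
    return(tc)
  }
  res <- mc_run(phantom$grid, mask_int(phantom), phantom$medium,
                phantom$fluor, probe_link_spec(probe, link),
                as.numeric(n_histories), as.integer(seed), 1L,
                numeric(0), bin_width, max_time, walk_thinning, nee_split)
  nb <- length(res$hist)
  tc <- time_curve(bin_edges = seq(0, by = bin_width, length.out = nb + 1L),
                   values = res$hist, kind = "FTPSF")
  attr(tc, "n_detected") <- res$n_detected
  attr(tc, "launched_weight") <- res$launched_weight
  attr(tc, "detected_weight") <- res$detected_weight
  attr(tc, "seed") <- as.integer(seed)
  tc
}

#' Time-resolved track-length deposit field
#'
#' Tallies, per fluorophore voxel and time bin, the attenuated path length
#' of photons launched either from the source fiber (`adjoint = FALSE`,
#' excitation fluence) or from the detector fiber with the detector's
#' angular response (`adjoint = TRUE`, detection probability field by
#' reciprocity). These are the two factors the pair estimator convolves.
#' Fields depend only on the respective endpoint, so they can be reused
#' across links sharing a source or detector position.
#'
#' @inheritParams simulate_ftpsf
#' @param adjoint Launch from the detector with the detector response.
#' @return An object of class `deposit_field`: list with `dep` (matrix,
#'   fluorophore voxel x time bin, per-history normalized), `voxel` (1-based
#'   flat indices), `Q` (detector source strength), `adjoint`, `seed`.
#' @export
deposit_field <- function(phantom, link, probe = probe_geometry(),
                          n_histories, seed = 1L, bin_width = 2,
                          max_time = 400, adjoint = FALSE) {
  stopifnot(inherits(phantom, "phantom"))
  res <- mc_deposit_run(phantom$grid, mask_int(phantom), phantom$medium,
                        phantom$fluor, probe_link_spec(probe, link),
                        as.numeric(n_histories), as.integer(seed),
                        bin_width, max_time, isTRUE(adjoint))
  structure(list(dep = res$dep, voxel = res$voxel, Q = res$Q,
                 nbins = res$nbins, bin_width = bin_width,
                 max_time = max_time, adjoint = isTRUE(adjoint),
                 seed = as.integer(seed), n_histories = n_histories),
            class = "deposit_field")
}

# Combine a forward and an adjoint deposit field (internal).
pair_combine <- function(phantom, fwd, adj, gates, bin_width, mode,
                         instant = FALSE, window_bins = 11L) {
  stopifnot(inherits(fwd, "deposit_field"), inherits(adj, "deposit_field"),
            !fwd$adjoint, adj$adjoint, fwd$nbins == adj$nbins)
  mc_pair_combine(fwd$dep, adj$dep, fwd$voxel,
                  as.integer(prod(phantom$grid$shape)),
                  phantom$grid$voxel_size^3, adj$Q, phantom$medium$mua,
                  phantom$fluor$gamma, phantom$fluor$tau,
                  as.numeric(gates), bin_width, as.integer(mode),
                  isTRUE(instant), as.integer(window_bins))
}

#' Compute time-gated sensitivity volumes
#'
#' Accumulates, per conversion voxel, the statistical weights of detected
#' fluorescent photons whose transport arrival time does not exceed the gate:
#' each detected photon contributes
#' `w0 * exp(-sum mua l) * mua * L` to the voxel where it was spawned, for
#' every requested gate at or after its arrival. Decay and quantum yield are
#' deliberately absent here - they live in the FPDF. Several gates can be
#' evaluated in a single pass over the same photon set, which also guarantees
#' elementwise gate monotonicity.
#'
#' @inheritParams simulate_ftpsf
#' @param gates Numeric vector of time gates (ps), all `> 0` (a gate of 0 is
#'   allowed and yields an all-zero volume).
#' @param gating Pair estimator only. `"cumulative"` accumulates all
#'   arrivals up to the gate (the step-indicator realization; guarantees
#'   elementwise gate monotonicity); `"instant"` takes the arrival density
#'   in the gate's own bin, which is the form consistent with gating an
#'   instantaneous response value.
#' @return If one gate: a `sensitivity_volume` (3-D array with attributes
#'   `grid`, `link`, `gate`, `n_histories`, `seed`). If several: a list of
#'   them, one per gate.
#' @export
compute_sensitivity <- function(phantom, link, probe = probe_geometry(),
                                gates, n_histories, seed = 1L,
                                max_time = NULL,
                                estimator = c("pair", "history"),
                                gating = c("cumulative", "instant"),
                                walk_thinning = 1, bin_width = 2,
                                nee_split = 1) {
  stopifnot(inherits(phantom, "phantom"), is.numeric(gates),
            length(gates) >= 1L)
  estimator <- match.arg(estimator)
  gating <- match.arg(gating)
  if (any(gates < 0)) stop("compute_sensitivity: gates must be >= 0")
  if (is.null(max_time)) max_time <- max(gates) + 13
  if (estimator == "pair") {
    nh <- ceiling(n_histories / 2)
    fwd <- deposit_field(phantom, link, probe, nh, seed,
                         bin_width, max_time, adjoint = FALSE)
    adj <- deposit_field(phantom, link, probe, nh, seed + 1L,
                         bin_width, max_time, adjoint = TRUE)
    res <- pair_combine(phantom, fwd, adj, gates, bin_width, mode = 2L,
                        instant = (gating == "instant"))
  } else {
    res <- mc_run(phantom$grid, mask_int(phantom), phantom$medium,
                  phantom$fluor, probe_link_spec(probe, link),
                  as.numeric(n_histories), as.integer(seed), 2L,
                  as.numeric(gates), 2, max_time, walk_thinning, nee_split)
  }
  link <- as_link(link)
  vols <- lapply(seq_along(gates), function(gi) {
    v <- array(res$sens[, gi], dim = phantom$grid$shape)
    structure(v, class = c("sensitivity_volume", "array"),
              grid = phantom$grid, link = link, gate = gates[gi],
              n_histories = n_histories, seed = as.integer(seed))
  })
  if (length(vols) == 1L) vols[[1]] else vols
}

#' @export
print.sensitivity_volume <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf(
    "<sensitivity_volume> %dx%dx%d, gate %g ps, %g histories, total weight %.4g\n",
    g$shape[1], g$shape[2], g$shape[3], attr(x, "gate"),
    attr(x, "n_histories"), sum(x)))
  invisible(x)
}

#' Trace individual photon histories
#'
#' Runs a few histories through the Monte Carlo engine with full event
#' recording: excitation trajectory vertices (position, time, weight),
#' fluorescent spawn records (position, time, statistical weight, emission
#' delay, conversion voxel) and detections. Intended for validation: the
#' recorded weights can be recomputed independently from the trajectory
#' geometry (Beer-Lambert attenuation along the recorded path).
#'
#' @inheritParams simulate_ftpsf
#' @param n_histories Number of histories to trace (keep small).
#' @param with_delay Sample exponential emission delays for spawned photons.
#' @return A list of histories; each has data frames `vertices`, `spawns`,
#'   `detections`.
#' @export
trace_history <- function(phantom, link, probe = probe_geometry(),
                          n_histories = 1L, seed = 1L, with_delay = FALSE,
                          max_time = 1000) {
  stopifnot(inherits(phantom, "phantom"))
  mc_trace(phantom$grid, mask_int(phantom), phantom$medium, phantom$fluor,
           probe_link_spec(probe, link), as.integer(n_histories),
           as.integer(seed), isTRUE(with_delay), max_time)
}

#' Exact voxel traversal of a straight segment
#'
#' Computes the exact intersection lengths of the segment `p0 -> p1` with the
#' voxels of a grid by incremental parametric (Amanatides-Woo) traversal.
#'
#' @param p0,p1 Length-3 endpoints (mm), inside the grid bounding box.
#' @param grid A [voxel_grid()].
#' @return A data.frame with 1-based voxel indices `ix`, `iy`, `iz` and the
#'   intersection `length` (mm), ordered from `p0` to `p1`. Zero rows when
#'   `p0 == p1`.
#' @export
traverse_voxels <- function(p0, p1, grid) {
  stopifnot(inherits(grid, "voxel_grid"), length(p0) == 3L, length(p1) == 3L)
  res <- mc_traverse_segment(as.numeric(p0), as.numeric(p1), grid)
  data.frame(ix = res$ix, iy = res$iy, iz = res$iz, length = res$length)
}
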