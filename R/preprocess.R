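#' Preprocessing parameters
#'
#' Settings for the measured-response processing chain that turns a noisy
#' fluorescence temporal response into an estimate of the underlying temporal
#' point spread function: Savitzky-Golay smoothing, Richardson-Lucy
#' instrument-response deconvolution and time-origin alignment.
#'
#' @param sg_window Odd Savitzky-Golay window length (samples).
#' @param sg_order Polynomial order, `< sg_window`.
#' @param rl_iterations Richardson-Lucy iterations, `>= 1`.
#' @param rl_accel Exponent of the accelerated multiplicative update
#'   (`1` = plain Richardson-Lucy).
#' @param edge_threshold Leading-edge detector: first bin at or above this
#'   fraction of the curve maximum.
#' @param time_shift Fixed alignment shift (ps) or `"auto"` to align against
#'   a reference curve.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(sg_window = 11L, sg_order = 3L,
                              rl_iterations = 20L, rl_accel = 1.5,
                              edge_threshold = 0.02, time_shift = "auto") {
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  stopifnot(sg_window %% 2L == 1L, sg_order < sg_window, rl_iterations >= 1L,
            rl_accel >= 1, edge_threshold > 0, edge_threshold < 1)
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 rl_iterations = as.integer(rl_iterations),
                 rl_accel = rl_accel, edge_threshold = edge_threshold,
                 time_shift = time_shift),
            class = "preprocess_params")
}

#' Smooth a fluorescence temporal response
#'
#' Savitzky-Golay filtering on the curve's own time grid; negative filter
#' outputs are clipped to zero (counts are physically nonnegative).
#'
#' @param curve A [time_curve()] with at least `sg_window` bins.
#' @param params A [preprocess_params()].
#' @return The smoothed [time_curve()].
#' @export
smooth_ftr <- function(curve, params = preprocess_params()) {
  stopifnot(inherits(curve, "time_curve"), inherits(params, "preprocess_params"))
  if (nrow(curve) < params$sg_window)
    stop("smooth_ftr: curve shorter than the Savitzky-Golay window")
  sm <- signal::sgolayfilt(curve$value, p = params$sg_order,
                           n = params$sg_window)
  curve_with_values(curve, pmax(sm, 0))
}

# Lower-triangular Toeplitz convolution matrix of kernel k (both signals
# sampled on the same grid starting at t = 0): (K u)_i = sum_j k[i-j+1] u_j.
conv_matrix <- function(k) {
  n <- length(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) K[j:n, j] <- k[seq_len(n - j + 1L)]
  K
}

#' Richardson-Lucy deconvolution of a response with the instrument function
#'
#' Iterative multiplicative deconvolution of a (smoothed) fluorescence
#' temporal response with the instrument response function, with the
#' exponentiated accelerated update `u <- u * r^q`. The kernel is normalized
#' to unit sum internally, so the total signal is conserved up to the IRF
#' normalization. Outputs are nonnegative by construction.
#'
#' @param ftr A [time_curve()], the (smoothed) response.
#' @param irf A [time_curve()] on the same grid; nonnegative, not all zero.
#' @param params A [preprocess_params()].
#' @return A [time_curve()] estimate of the underlying FTPSF shape.
#' @export
deconvolve_irf <- function(ftr, irf, params = preprocess_params()) {
  stopifnot(inherits(ftr, "time_curve"), inherits(irf, "time_curve"),
            inherits(params, "preprocess_params"))
  if (!same_grid(ftr, irf))
    stop("deconvolve_irf: FTR and IRF must share one time grid")
  k <- irf$value
  if (any(k < 0) || sum(k) <= 0)
    stop("deconvolve_irf: IRF must be nonnegative and not all zero")
  k <- k / sum(k)
  d <- ftr$value
  if (sum(d) == 0) return(curve_with_values(ftr, d, kind = "FTPSF"))
  K <- conv_matrix(k)
  u <- rep(mean(d), length(d))
  q <- params$rl_accel
  for (it in seq_len(params$rl_iterations)) {
    Ku <- as.numeric(K %*% u)
    r <- ifelse(Ku > 0, d / Ku, ifelse(d > 0, 1, 0))
    corr <- as.numeric(crossprod(K, r))  # adjoint; columns of K sum to <= 1
    csum <- colSums(K)
    corr <- ifelse(csum > 0, corr / csum, 1)
    u <- u * corr^q
  }
  curve_with_values(ftr, pmax(u, 0), kind = "FTPSF")
}

# First bin index at or above threshold * max(values); NA if undetectable.
leading_edge_index <- function(values, threshold) {
  m <- max(values)
  if (m <= 0) return(NA_integer_)
  idx <- which(values >= threshold * m)
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

#' Align the time origin of a curve
#'
#' Translates a curve along its time axis so that its leading edge (first bin
#' reaching a configurable fraction of the maximum) coincides with the
#' leading edge of a reference curve - typically a modelled FTPSF, whose
#' absolute timing is trusted. Alternatively a fixed shift (ps) can be given.
#' Shifts are rounded to whole bins; vacated bins are zero-filled. The
#' applied shift is recorded in the `shift_ps` attribute.
#'
#' @param curve A [time_curve()].
#' @param reference A reference [time_curve()] on the same grid, or a numeric
#'   shift in ps.
#' @param params A [preprocess_params()].
#' @return The aligned [time_curve()].
#' @export
align_time_origin <- function(curve, reference,
                              params = preprocess_params()) {
  stopifnot(inherits(curve, "time_curve"))
  bw <- curve_bin_width(curve)
  if (is.numeric(reference) && length(reference) == 1L) {
    shift_ps <- reference
  } else {
    stopifnot(inherits(reference, "time_curve"))
    ec <- leading_edge_index(curve$value, params$edge_threshold)
    er <- leading_edge_index(reference$value, params$edge_threshold)
    if (is.na(ec) || is.na(er))
      stop("align_time_origin: leading edge undetectable")
    shift_ps <- (er - ec) * bw
  }
  nb <- round(shift_ps / bw)
  v <- curve$value
  n <- length(v)
  out <- numeric(n)
  if (nb >= 0) {
    if (nb < n) out[(nb + 1L):n] <- v[seq_len(n - nb)]
  } else {
    if (-nb < n) out[seq_len(n + nb)] <- v[(-nb + 1L):n]
  }
  res <- curve_with_values(curve, out)
  attr(res, "shift_ps") <- nb * bw
  res
}

#' Full response-processing chain for one link
#'
#' Convenience wrapper: smooth, deconvolve with the IRF, align against a
#' reference FTPSF (or fixed shift), and extract the gated measurement value.
#'
#' @param ftr,irf [time_curve()]s on one grid.
#' @param gate Gate time (ps).
#' @param reference Reference curve or numeric shift for alignment;
#'   `NULL` skips alignment.
#' @param params A [preprocess_params()].
#' @return List with the processed `curve` and the scalar `value` at the
#'   gate.
#' @export
preprocess_ftr <- function(ftr, irf, gate, reference = NULL,
                           params = preprocess_params()) {
  cur <- smooth_ftr(ftr, params)
  cur <- deconvolve_irf(cur, irf, params)
  if (!is.null(reference)) cur <- align_time_origin(cur, reference, params)
  list(curve = cur, value = gate_value(cur, gate))
}
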