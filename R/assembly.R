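#' Gating strategies for FPDF reconstruction
#'
#' A strategy prescribes, for each of the (at least three) FPDF
#' reconstructions, which source-detector distances are used, the time gate
#' attached to each distance, and the resulting common average migration
#' velocity `v = R / t` (constant across the distances of one entry by
#' construction).
#'
#' `build_strategy1` uses a single gate for all distances: entry m uses only
#' distance `R_m`, so the three velocities are `R_m / gate`.
#'
#' `build_strategy2` maximizes the number of links per reconstruction under
#' the constraint that no gate exceeds `base_gate` (later gates sit too close
#' to the response maximum to qualify as early): entry 1 uses all three
#' distances with gates scaled as `t_m = R_m / R_1 * base_gate`; entry 2 uses
#' the two shortest distances at `base_gate` and `R_3/R_2 * base_gate`;
#' entry 3 uses the two longest with the shorter gate pair. Gates are rounded
#' to whole picoseconds (the exact values are kept in `gate_exact`); the
#' entry velocity always uses the unrounded ratio.
#'
#' @param sr_distances Distinct source-detector distances (mm), decreasing
#'   order `R1 > R2 > R3` expected for strategy 2.
#' @param gate,base_gate Gate (ps), `> 0`.
#' @return An object of class `strategy`: a list of entries, each with
#'   `used_sr_distances`, `gates` (named by distance), `gate_exact`,
#'   `velocity`, `expected_links_per_position`.
#' @examples
#' build_strategy2(c(3.3, 2.2, 1.1), 200)
#' @export
build_strategy1 <- function(sr_distances = c(3.3, 2.2, 1.1), gate = 200) {
  if (anyDuplicated(sr_distances)) stop("build_strategy1: duplicate distances")
  stopifnot(gate > 0)
  entries <- lapply(sr_distances, function(R) {
    list(used_sr_distances = R,
         gates = stats::setNames(gate, format(R)),
         gate_exact = stats::setNames(gate, format(R)),
         velocity = R / gate,
         expected_links_per_position = 1L)
  })
  structure(list(entries = entries, kind = "strategy1"), class = "strategy")
}

#' @rdname build_strategy1
#' @export
build_strategy2 <- function(sr_distances = c(3.3, 2.2, 1.1), base_gate = 200) {
  if (length(sr_distances) != 3L || anyDuplicated(sr_distances))
    stop("build_strategy2: exactly three distinct distances are required")
  stopifnot(base_gate > 0)
  R <- sort(sr_distances, decreasing = TRUE)
  # Each entry fixes one exact velocity; the per-distance exact gates follow
  # from R/t = const and are truncated to whole picoseconds for labelling and
  # simulation (133.33 -> 133, 66.67 -> 66), matching the published scheme.
  mk <- function(Rs, v) {
    te <- Rs / v
    list(used_sr_distances = Rs,
         gates = stats::setNames(floor(te + 1e-9), format(Rs)),
         gate_exact = stats::setNames(te, format(Rs)),
         velocity = v,
         expected_links_per_position = length(Rs))
  }
  entries <- list(
    mk(R, R[1] / base_gate),          # all three distances, v1 = R1/t1
    mk(R[2:3], R[2] / base_gate),     # two shortest, v2 = R2/t1
    mk(R[1:2], 2 * R[1] / base_gate)  # two longest, v3 = R1/(t1/2) = 2 v1
  )
  structure(list(entries = entries, kind = "strategy2"), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<%s> %d reconstructions\n", x$kind, length(x$entries)))
  for (i in seq_along(x$entries)) {
    e <- x$entries[[i]]
    cat(sprintf("  %d: R = {%s} mm, gates = {%s} ps, v = %g mm/ps\n", i,
                paste(e$used_sr_distances, collapse = ", "),
                paste(e$gates, collapse = ", "), e$velocity))
  }
  invisible(x)
}

# All (sr_distance, gate) pairs a strategy needs, as a data.frame.
strategy_pairs <- function(strategy) {
  do.call(rbind, lapply(seq_along(strategy$entries), function(i) {
    e <- strategy$entries[[i]]
    data.frame(entry = i, sr_distance = e$used_sr_distances,
               gate = as.numeric(e$gates))
  }))
}

#' Translate sensitivity volumes across scan rows
#'
#' Sensitivity volumes computed for the middle scan row are reused for the
#' other rows by translating them along the row-advance axis by whole-voxel
#' shifts (valid because the background medium is laterally homogeneous).
#' A non-integer voxel shift is an error unless `round_shift = TRUE`.
#'
#' @param volume A `sensitivity_volume`.
#' @param shift_mm Signed translation along the row axis (mm).
#' @param axis Translation axis: 1 (x) or 2 (y).
#' @param round_shift Round a fractional voxel shift to the nearest voxel.
#' @return The translated volume (values leaving the grid are dropped,
#'   entering ones are zero).
#' @export
replicate_rows <- function(volume, shift_mm, axis = 2L, round_shift = FALSE) {
  grid <- attr(volume, "grid")
  h <- grid$voxel_size
  sv <- shift_mm / h
  if (abs(sv - round(sv)) > 1e-9) {
    if (!round_shift)
      stop("replicate_rows: shift is not a whole number of voxels")
    sv <- round(sv)
  }
  sv <- as.integer(round(sv))
  out <- array(0, dim = dim(volume))
  n <- dim(volume)[axis]
  if (abs(sv) < n) {
    src <- if (sv >= 0) seq_len(n - sv) else seq(1L - sv, n)
    dst <- if (sv >= 0) seq(1L + sv, n) else seq_len(n + sv)
    idx_src <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx_dst <- idx_src
    idx_src[[axis]] <- src
    idx_dst[[axis]] <- dst
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(unclass(volume)), idx_src,
                                                list(drop = FALSE))))))
  }
  attrs <- attributes(volume)
  attrs$dim <- dim(out)
  attributes(out) <- attrs
  lk <- attr(out, "link")
  if (!is.null(lk)) {
    ax_names <- if (axis == 1L) c("sx", "dx") else c("sy", "dy")
    for (a in ax_names) lk[[a]] <- lk[[a]] + sv * h
    attr(out, "link") <- lk
  }
  out
}

#' Assemble the gated linear system W f = g
#'
#' Builds the sensitivity matrix `W` (one flattened sensitivity volume per
#' row) and the measurement vector `g` (gated values times a calibration
#' scalar) for one strategy entry. Rows follow the supplied link order
#' (zigzag scan order with distances cycled fastest, as produced by
#' [scan_links()]).
#'
#' @param sensitivities List of `sensitivity_volume`s, one per link row, in
#'   row order. Each must carry `link` and `gate` attributes matching the
#'   corresponding measurement.
#' @param measurements Numeric vector of gated measurement values, same
#'   length and order.
#' @param entry The strategy entry (an element of `strategy$entries`).
#' @param calibration Scalar (or per-row vector) factor applied to the
#'   measurements to bring them to the sensitivity-model scale.
#' @return An object of class `linear_system`: list with matrix `W` (J x I),
#'   vector `g`, `grid`, `meta` (per-row link/gate data.frame), `entry`.
#' @export
assemble <- function(sensitivities, measurements, entry, calibration = 1) {
  stopifnot(is.list(sensitivities), length(sensitivities) >= 1L,
            length(measurements) == length(sensitivities))
  grid <- attr(sensitivities[[1L]], "grid")
  I <- prod(grid$shape)
  J <- length(sensitivities)
  need <- entry$used_sr_distances
  meta <- do.call(rbind, lapply(sensitivities, function(v) {
    lk <- attr(v, "link")
    data.frame(sr_distance = lk$sr_distance, gate = attr(v, "gate"),
               sx = lk$sx, sy = lk$sy, dx = lk$dx, dy = lk$dy)
  }))
  for (j in seq_len(J)) {
    R <- meta$sr_distance[j]
    if (!any(abs(R - need) < 1e-9))
      stop("assemble: row ", j, " has sr_distance ", R,
           " not used by this entry")
    want_gate <- as.numeric(entry$gates[which.min(abs(need - R))])
    if (abs(meta$gate[j] - want_gate) > 1e-9)
      stop("assemble: row ", j, " gate ", meta$gate[j],
           " does not match the entry gate ", want_gate)
  }
  W <- matrix(0, J, I)
  for (j in seq_len(J)) W[j, ] <- as.numeric(sensitivities[[j]])
  g <- as.numeric(measurements) * calibration
  structure(list(W = W, g = g, grid = grid, meta = meta, entry = entry),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("<linear_system> W: %d x %d, v = %g mm/ps\n",
              nrow(x$W), ncol(x$W), x$entry$velocity))
  invisible(x)
}

#' Calibrate gated measurements against a reference forward model
#'
#' The coupling between measured counts and the sensitivity-model scale (the
#' proportionality constant of the linear model plus the instrument coupling
#' factor) is resolved by calibration against a known reference FPDF volume:
#' for each (distance, gate) group of rows the scalar is
#' `sum_j (w_j . f_ref) / sum_j g_j` over the group's links. Applied to the
#' raw measurements this brings them onto the model scale group by group.
#'
#' @param system A [assemble()]d `linear_system` with *uncalibrated* `g`.
#' @param f_ref Reference FPDF volume (array or vector of length I).
#' @return The system with calibrated `g`; calibration factors are stored in
#'   `calibration` (one per (distance, gate) group).
#' @export
calibrate_system <- function(system, f_ref) {
  stopifnot(inherits(system, "linear_system"))
  f <- as.numeric(f_ref)
  if (length(f) != ncol(system$W))
    stop("calibrate_system: reference volume size mismatch")
  pred <- as.numeric(system$W %*% f)
  grp <- interaction(system$meta$sr_distance, system$meta$gate, drop = TRUE)
  fac <- numeric(nlevels(grp))
  names(fac) <- levels(grp)
  for (lv in levels(grp)) {
    j <- grp == lv
    s <- sum(system$g[j])
    fac[lv] <- if (s > 0) sum(pred[j]) / s else 1
  }
  system$g <- system$g * as.numeric(fac[as.character(grp)])
  system$calibration <- fac
  system
}
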