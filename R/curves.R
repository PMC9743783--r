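#' Binned time-resolved signal
#'
#' Container for a uniformly binned time curve: a modelled temporal point
#' spread function (FTPSF), a measured/synthetic fluorescence temporal
#' response (FTR) or an instrument response function (IRF).
#'
#' @param bin_edges Strictly increasing, uniform bin edges (ps); length
#'   `length(values) + 1`.
#' @param values Nonnegative per-bin detected weight or counts.
#' @param kind One of `"FTPSF"`, `"FTR"`, `"IRF"`.
#' @return An object of class `time_curve`: a data.frame with columns
#'   `time_ps` (bin centres) and `value`, plus attributes `bin_edges`,
#'   `bin_width`, `kind`.
#' @export
time_curve <- function(bin_edges, values, kind = c("FTPSF", "FTR", "IRF")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(bin_edges), is.numeric(values),
            length(bin_edges) == length(values) + 1L)
  if (any(values < 0)) stop("time_curve: values must be >= 0")
  w <- diff(bin_edges)
  if (any(w <= 0) || diff(range(w)) > 1e-9 * mean(w))
    stop("time_curve: bin edges must be uniform and increasing")
  out <- data.frame(time_ps = (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2,
                    value = as.numeric(values))
  structure(out, class = c("time_curve", "data.frame"),
            bin_edges = as.numeric(bin_edges), bin_width = mean(w),
            kind = kind)
}

curve_bin_width <- function(curve) attr(curve, "bin_width")

# Rebuild a time_curve with new values, keeping grid and kind.
curve_with_values <- function(curve, values, kind = attr(curve, "kind")) {
  tc <- time_curve(attr(curve, "bin_edges"), values, kind)
  for (a in c("shift_ps")) if (!is.null(attr(curve, a))) attr(tc, a) <- attr(curve, a)
  tc
}

same_grid <- function(a, b) {
  ea <- attr(a, "bin_edges"); eb <- attr(b, "bin_edges")
  length(ea) == length(eb) && all(abs(ea - eb) < 1e-9)
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf("<time_curve:%s> %d bins of %g ps, peak %.4g at %g ps\n",
              attr(x, "kind"), nrow(x), curve_bin_width(x),
              max(x$value), x$time_ps[which.max(x$value)]))
  invisible(x)
}

#' Gated value of a time curve
#'
#' Linearly interpolates the curve (defined at bin centres) at the requested
#' gate time. This is the measurement datum extracted from a processed
#' response for a given receiver gating delay.
#'
#' @param curve A [time_curve()].
#' @param gate Gate time (ps), inside the span of bin centres.
#' @return Interpolated scalar value.
#' @export
gate_value <- function(curve, gate) {
  stopifnot(inherits(curve, "time_curve"), is.numeric(gate),
            length(gate) == 1L)
  if (gate < min(curve$time_ps) || gate > max(curve$time_ps))
    stop("gate_value: gate lies outside the curve support")
  stats::approx(curve$time_ps, curve$value, xout = gate)$y
}

#' Read/write time curves as two-column TSV
#'
#' The on-disk format is a plain TSV with columns `time_ps` (bin centres)
#' and `value`; the kind is stored in a comment header line.
#'
#' @param curve A [time_curve()].
#' @param path File path.
#' @return `write_time_curve` returns `path` invisibly; `read_time_curve`
#'   returns a [time_curve()].
#' @export
write_time_curve <- function(curve, path) {
  stopifnot(inherits(curve, "time_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s bin_width=%.17g t0=%.17g", attr(curve, "kind"),
                     curve_bin_width(curve), attr(curve, "bin_edges")[1]), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_time_curve
#' @export
read_time_curve <- function(path) {
  hdr <- readLines(path, n = 1L)
  kind <- sub(".*kind=(\\S+).*", "\\1", hdr)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  bw <- as.numeric(sub(".*bin_width=(\\S+).*", "\\1", hdr))
  t0 <- as.numeric(sub(".*t0=(\\S+).*", "\\1", hdr))
  edges <- seq(t0, by = bw, length.out = nrow(df) + 1L)
  time_curve(edges, df$value, kind)
}
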