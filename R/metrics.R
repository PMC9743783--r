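#' Reconstruction quality metrics
#'
#' `kcor` is the Pearson correlation coefficient between a reconstructed
#' volume and its reference model over all voxels,
#' \deqn{k_{cor} = \frac{\sum_i (x_i^{tom}-\bar x^{tom})(x_i^{src}-\bar x^{src})}
#'   {(I-1)\,\Delta x^{tom}\,\Delta x^{src}},}
#' and `kdev` is the root-mean-square voxel difference normalized by the
#' sample standard deviation of the reference,
#' \deqn{k_{dev} = \frac{\sqrt{\tfrac1I \sum_i (x_i^{tom}-x_i^{src})^2}}
#'   {\Delta x^{src}}.}
#' Standard deviations use the (I-1) denominator. A reconstruction close to
#' the model has `kcor` near 1 and `kdev` near 0; `kcor` is invariant under
#' positive affine rescaling of the reconstruction, `kdev` is not.
#'
#' @param tom Reconstructed volume (array or vector).
#' @param src Reference model volume, congruent with `tom`.
#' @return A scalar; `kcor` lies in `[-1, 1]`, `kdev` is `>= 0`.
#' @export
kcor <- function(tom, src) {
  x <- as.numeric(tom); y <- as.numeric(src)
  if (length(x) != length(y)) stop("kcor: volumes must be congruent")
  I <- length(x)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("kcor: undefined for zero-variance volumes")
  sum((x - mean(x)) * (y - mean(y))) / ((I - 1) * sx * sy)
}

#' @rdname kcor
#' @export
kdev <- function(tom, src) {
  x <- as.numeric(tom); y <- as.numeric(src)
  if (length(x) != length(y)) stop("kdev: volumes must be congruent")
  sy <- stats::sd(y)
  if (sy == 0) stop("kdev: undefined for a zero-variance reference")
  sqrt(mean((x - y)^2)) / sy
}
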