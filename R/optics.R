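# Speed of light in vacuum, mm/ps.
C0_MM_PS <- 0.299792458

#' Optical properties of the background medium
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy factor and refractive index of a homogeneous turbid medium.
#' All lengths in the package are millimetres, times picoseconds, so rates
#' are mm^-1 and speeds mm/ps.
#'
#' @param mua Absorption coefficient (mm^-1), `>= 0`.
#' @param mus Scattering coefficient (mm^-1), `> 0`.
#' @param g Scattering anisotropy factor (mean cosine of the single-scatter
#'   deflection angle), in `[0, 1)`.
#' @param n Refractive index, `>= 1`.
#' @return An object of class `optical_medium`.
#' @examples
#' # the tissue-mimicking phantom material used throughout the package docs
#' optical_medium(mua = 0.01, mus = 2.63, g = 0.62, n = 1.521)
#' @export
optical_medium <- function(mua = 0.01, mus = 2.63, g = 0.62, n = 1.521) {
  stopifnot(is.numeric(mua), is.numeric(mus), is.numeric(g), is.numeric(n),
            length(mua) == 1L, length(mus) == 1L, length(g) == 1L,
            length(n) == 1L)
  if (mua < 0) stop("invalid medium: mua must be >= 0")
  if (mus <= 0) stop("invalid medium: mus must be > 0")
  if (g < 0 || g >= 1) stop("invalid medium: g must lie in [0, 1)")
  if (n < 1) stop("invalid medium: n must be >= 1")
  if (mus * (1 - g) <= 0)
    stop("invalid medium: reduced scattering mus * (1 - g) must be > 0")
  structure(list(mua = mua, mus = mus, g = g, n = n),
            class = "optical_medium")
}

#' Fluorophore parameters
#'
#' @param muaf Fluorophore absorption coefficient (mm^-1), `>= 0`.
#' @param gamma Fluorescence quantum yield, in `[0, 1]`.
#' @param tau Fluorescence lifetime (ps), `>= 0`.
#' @return An object of class `fluorophore_props`.
#' @export
fluorophore_props <- function(muaf = 0.01, gamma = 0.2, tau = 900) {
  stopifnot(is.numeric(muaf), is.numeric(gamma), is.numeric(tau),
            length(muaf) == 1L, length(gamma) == 1L, length(tau) == 1L)
  if (muaf < 0) stop("invalid fluorophore: muaf must be >= 0")
  if (gamma < 0 || gamma > 1) stop("invalid fluorophore: gamma must lie in [0, 1]")
  if (tau < 0) stop("invalid fluorophore: tau must be >= 0")
  structure(list(muaf = muaf, gamma = gamma, tau = tau),
            class = "fluorophore_props")
}

#' Set of average photon migration velocities
#'
#' One velocity per reconstructed distribution of the fluorescence parameter
#' distribution function (FPDF). Parameter separation needs at least three
#' pairwise distinct velocities to be well posed.
#'
#' @param v Numeric vector of average migration velocities (mm/ps), all
#'   positive and pairwise distinct.
#' @return An object of class `velocity_set`.
#' @export
velocity_set <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1L)
  if (any(v <= 0)) stop("invalid velocity set: all velocities must be > 0")
  if (anyDuplicated(v)) stop("invalid velocity set: velocities must be pairwise distinct")
  structure(list(v = as.numeric(v)), class = "velocity_set")
}

#' Photon diffusion coefficient
#'
#' `D = 1 / (3 mus (1 - g))`, the standard scattering-only diffusion length
#' used in early-photon work.
#'
#' @param medium An [optical_medium()].
#' @return Diffusion coefficient D in mm.
#' @export
diffusion_coefficient <- function(medium) {
  stopifnot(inherits(medium, "optical_medium"))
  denom <- 3 * medium$mus * (1 - medium$g)
  if (denom <= 0) stop("invalid medium: mus * (1 - g) is degenerate")
  1 / denom
}

#' Light velocity in the medium
#'
#' @param medium An [optical_medium()].
#' @return c = c0 / n in mm/ps.
#' @export
light_speed <- function(medium) {
  stopifnot(inherits(medium, "optical_medium"))
  if (medium$n < 1) stop("invalid medium: n must be >= 1")
  C0_MM_PS / medium$n
}

#' Average photon migration velocity for a gated source-detector link
#'
#' The mass-centre velocity of the instantaneous photon distribution along the
#' average trajectory is approximated by the source-detector distance divided
#' by the time gate, v = R / t.
#'
#' @param R Source-detector distance (mm), `> 0`.
#' @param t Time gate (ps), `> 0`.
#' @return Velocity in mm/ps.
#' @examples
#' average_velocity(3.3, 200)  # 0.0165 mm/ps
#' @export
average_velocity <- function(R, t) {
  stopifnot(is.numeric(R), is.numeric(t))
  if (any(R <= 0) || any(t <= 0))
    stop("average_velocity: R and t must be > 0")
  R / t
}

#' Fluorescence parameter distribution function (closed form)
#'
#' Evaluates the FPDF
#' \deqn{f = \frac{4 D c \gamma \mu_{af}}{v^2 \tau + 4 D c}}
#' for a homogeneous medium/fluorophore pair at average migration velocity
#' `v`. The FPDF is the quantity reconstructed linearly from gated
#' early-photon measurements before the absorption coefficient and lifetime
#' are separated.
#'
#' @param medium An [optical_medium()].
#' @param fluor A [fluorophore_props()].
#' @param v Average photon migration velocity (mm/ps), `>= 0`; may be a
#'   vector.
#' @return FPDF value(s) in mm^-1. Always in `[0, gamma * muaf]`, strictly
#'   decreasing in `v` when `tau > 0`, and equal to `gamma * muaf` at
#'   `v = 0` or `tau = 0`.
#' @examples
#' med <- optical_medium()
#' flu <- fluorophore_props()
#' fpdf_value(med, flu, average_velocity(3.3, 200))
#' @export
fpdf_value <- function(medium, fluor, v) {
  stopifnot(inherits(medium, "optical_medium"),
            inherits(fluor, "fluorophore_props"), is.numeric(v))
  if (any(v < 0)) stop("fpdf_value: v must be >= 0")
  fdc <- 4 * diffusion_coefficient(medium) * light_speed(medium)
  fdc * fluor$gamma * fluor$muaf / (v^2 * fluor$tau + fdc)
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf(
    "<optical_medium> mua=%g mm^-1, mus=%g mm^-1, g=%g, n=%g (D=%.5f mm, c=%.5f mm/ps)\n",
    x$mua, x$mus, x$g, x$n, diffusion_coefficient(x), light_speed(x)))
  invisible(x)
}

#' @export
print.fluorophore_props <- function(x, ...) {
  cat(sprintf("<fluorophore_props> muaf=%g mm^-1, gamma=%g, tau=%g ps\n",
              x$muaf, x$gamma, x$tau))
  invisible(x)
}
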