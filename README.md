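# earlyflt

Early-photon mesoscopic **fluorescence molecular lifetime tomography**
(FMLT) in R: simulate time-resolved fluorescence measurements of a turbid
phantom by Monte Carlo, reconstruct the fluorescence parameter distribution
function (FPDF) from time-gated early-photon data with a hybrid ART-FIST-TV
solver, and separate the fluorophore absorption coefficient and
fluorescence lifetime maps by per-voxel damped least squares.

The package is aimed at researchers in diffuse optics / fluorescence
tomography who want a self-contained, testable implementation of the
early-photon lifetime method: every stage — phantom, transport, response
preprocessing, system assembly, inversion, separation — is an exported
function, and a synthetic-data generator makes the whole chain runnable
without any measured data.

## The model

For photons on the leading edge of the fluorescence temporal point spread
function, the time-domain fluorescence signal is linear in the FPDF

```
f(r) = 4 D c γ μ_af(r) / (v² τ(r) + 4 D c)
```

with `D = 1/(3 μs (1−g))` the diffusion coefficient, `c = c0/n` the light
speed in the medium, `γ` the quantum yield and `v = R/t` the average photon
migration velocity of a source–detector link at distance `R` gated at time
`t`. Gated measurements `g` and Monte Carlo sensitivity functions `W`
(per-voxel detected weights of first-order fluorescence conversions) give a
linear system `W f = g` per velocity; reconstructing `f` at three distinct
velocities and inverting, per voxel,

```
4Dcγ · μ_af − f_m v_m² · τ = 4Dc f_m     (m = 1, 2, 3)
```

in the damped least-squares sense yields `μ_af(r)` and `τ(r)`.

## Worked example

The closed-form FPDF at the phantom-study parameters (tissue-mimicking
block: `μa = 0.01`, `μs = 2.63` mm⁻¹, `g = 0.62`, `n = 1.521`; Cy5-like
fluorophore: `μ_af = 0.01` mm⁻¹, `γ = 0.2`, `τ = 900` ps), at the four
gated velocities of the two scanning strategies:

```r
library(earlyflt)
med <- optical_medium(mua = 0.01, mus = 2.63, g = 0.62, n = 1.521)
flu <- fluorophore_props(muaf = 0.01, gamma = 0.2, tau = 900)
signif(fpdf_value(med, flu, c(0.0165, 0.011, 0.0055, 0.033)), 2)
#> [1] 0.00100 0.00140 0.00180 0.00042
```

The strategy-2 bookkeeping (which offsets, gates and velocities feed each
of the three FPDF reconstructions):

```r
build_strategy2(c(3.3, 2.2, 1.1), 200)
#> <strategy2> 3 reconstructions
#>   1: R = {3.3, 2.2, 1.1} mm, gates = {200, 133, 66} ps, v = 0.0165 mm/ps
#>   2: R = {2.2, 1.1} mm, gates = {200, 100} ps, v = 0.011 mm/ps
#>   3: R = {3.3, 2.2} mm, gates = {100, 66} ps, v = 0.033 mm/ps
```

Noiseless round trip of the parameter separation — generate three FPDF
values at those velocities, invert at damping 0:

```r
v <- c(0.0165, 0.011, 0.033)
f <- fpdf_value(med, flu, v)
separate_voxel(f, v, med, gamma = 0.2, separation_params(omega = 0))
#> $muaf
#> [1] 0.01
#> $tau
#> [1] 900
#> $valid
#> [1] TRUE
```

i.e. the fluorophore absorption coefficient (0.01 mm⁻¹) and lifetime
(900 ps) are recovered exactly.

A complete reduced synthetic experiment (digital phantom → Monte Carlo →
response synthesis → preprocessing → assembly → ART-FIST-TV → separation)
runs through `run_experiment()`; see the methods vignette
(`vignettes/earlyflt-methods.Rmd`) for the model, the estimator design and
the validation scale.

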