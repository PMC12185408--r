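# cellshock

State-equation analysis of single-cell deformation under shock loading.

When a single adherent cell is exposed to a sub-millisecond hydraulic
pressure ramp (a weak shock wave), active biological processes have no time
to respond and the change in the cell's projected area reflects its passive
material behaviour. The observable is the final-to-initial area ratio
**ζ = A_final / A_initial**, recorded by a high-speed camera synchronized
with a pressure sensor. `cellshock` implements the complete analysis chain
for such experiments, for biophysicists and image-analysis practitioners
who want to fit and probe area–pressure state equations of single cells:

- **Synthetic data** emulating the study design: ~198 cells with Gaussian
  initial area/perimeter and uniform orientation, peak pressures clustered
  into 15 levels over 156.48–3603.85 kPa, constant-rate ramps (≤0.1 ms at
  2×10⁵ fps), state-equation responses with multiplicative water-exchange
  fluctuation, occasional detachment, and optional rendered 160×48 px
  12-bit frame stacks with ground-truth masks.
- **Imaging**: Otsu + morphology + largest-component segmentation with
  marching-squares subpixel contours; shape descriptors (area, perimeter,
  orientation, elongation, circularity, compactness, convexity, solidity);
  waveform-synchronized initial/final frame selection with a detachment
  rule.
- **Mechanics**: the compression/shear decoupling `F = s·I × S` with
  det S = 1 — shear distorts shape, only compression changes area
  (`s = sqrt(ζ)`).
- **State equations**: three families linking pressure and area, with
  p̂ = (p − p0)/p_ref,

  | family | form | inflection |
  |---|---|---|
  | exponential | `A = A0·exp(B0·p̂ + B′p̂²/2)` | at `(B0 + B′p̂)² = −B′` iff `B′ < 0` |
  | logarithmic-integral | `(p−p0)/p0 = exp(α1·li(A/A0))` | at `A/A0 = 1/α1` for `0 < α1 < 1` |
  | Tait-like | `p = α3·p0·(A/A0)^κ + p0` | none (fixed-sign curvature) |

  plus derivative/inflection analysis, a two-compartment
  (cytoplasm + nucleus) refinement, discrete isobaric trajectories and a
  loading-rate continuation of the maximum-deformation-rate locus.
- **Inference**: Shapiro–Wilk / Kolmogorov–Smirnov validation of the shape
  distributions, greedy peak-pressure grouping (≤5% variation, >3 members),
  per-group linear fits of ζ against initial area, nonlinear least-squares
  state-equation fitting (`fit_state_equation()`, a classed model object
  with `print`/`summary`/`coef`/`confint`/`predict`/`simulate`/`plot`
  methods), and a Monte-Carlo parameter-recovery harness.

See the methods vignette (`vignettes/cellshock-methods.Rmd`) for the models,
assumptions, parameter choices and limitations.

## Worked example

```r
library(cellshock)

ds <- generate_dataset(list(seed = 1))   # the 15-level, n = 198 design
ds
#> Synthetic shock-loading dataset: 198 records, 15 pressure levels
#>   pmax 253.651-3467.07 kPa, zeta 1.5-13.4, 2 detached

fit <- fit_state_equation(ds$records, "tait", seed = 1)
summary(fit)
#> State-equation fit [tait family]
#> n = 196  residual df = 194
#>        Estimate Std. Error t value
#> kappa  1.498717   0.013566 110.477
#> alpha3 0.798212   0.019026  41.953
#> Residual standard error (log zeta): 0.0522
```

The generator's true parameters are κ = 1.5, α3 = 0.8; the fit recovers
them within one standard error from 196 non-detached records carrying 5%
multiplicative fluctuation (the two detached records are excluded because
their peak pressure is censored at the detachment frame). The residual
standard error ≈0.05 on the log-ζ scale is the fluctuation amplitude
itself.

Inflection analysis of an exponential-family curve with a decaying area
modulus:

```r
m <- state_equation("exponential", A0 = 300, p0 = 100, Bprime = -0.25)
find_inflection(m)
#> Inflection point (exponential family): p_k = 300 kPa, A_k = 1344.51 um^2, zeta_k = 4.48169
```

i.e. the maximum area-growth rate occurs at nondimensional overpressure
p̂ = 2, the analytic root of `(1 + B′p̂)² = −B′`.

An end-to-end run (simulate → group → fit → figures + manifest):

```r
run <- run_pipeline(list(seed = 20260920), out_dir = "run1")
run$objects$grouping   # 15 recovered pressure levels
run$objects$fit        # converged Tait fit
```

A thin command-line wrapper over the same functions ships in
`inst/cli/cellshock.R` (`simulate`, `group`, `fit`, `run-all`).

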