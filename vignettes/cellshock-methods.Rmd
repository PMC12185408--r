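---
title: "Methods: state-equation analysis of single-cell deformation under shock loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-equation analysis of single-cell deformation under shock loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellshock)
```

## The problem

When a single adherent cell is hit by a weak shock wave in a fluid-filled
chamber, its projected area changes within a fraction of a millisecond --
fast enough that active biological processes cannot respond, so the
deformation reflects the cell's passive material behaviour. The observable
is the final-to-initial area ratio

$$\zeta = A_\mathrm{final} / A_\mathrm{initial},$$

measured from top-down high-speed images synchronized with a pressure
sensor. `cellshock` implements the full analysis chain for such
experiments: a synthetic-data generator that emulates the study design, an
imaging pipeline (segmentation, morphometrics, frame selection), the
kinematic decoupling of compression and shear, three candidate area-pressure
*state equations* with their curvature analysis, and a statistical layer
that groups records by peak pressure and fits the state equations by
nonlinear least squares.

Because no measured dataset is distributed with the package, every analysis
here runs on synthetic data whose statistical structure mirrors the
experimental design: 198 cells, peak pressures clustered into fifteen
levels spanning roughly 156–3604 kPa, Gaussian initial areas and
perimeters, uniform initial orientation, sub-0.1 ms constant-rate pressure
ramps sampled at 2×10^5 frames per second, and 160×48 px, 0.75 µm/px,
12-bit frames.

## Kinematic decoupling

Over the ~0.1 ms loading window the deformation is treated as the product
of an isotropic in-plane stretch $s\,I$ and a unit-determinant shear
$S = \begin{pmatrix}1 & \gamma_x\\ \gamma_y & 1\end{pmatrix}\big/
\sqrt{1-\gamma_x\gamma_y}$ (defined for $\gamma_x\gamma_y<1$). By
construction $\det S = 1$: shear distorts the outline without changing the
enclosed area, and the whole area change is carried by the stretch,
$A_\mathrm{final}/A_\mathrm{initial} = s^2$. `apply_deformation()` realizes
the map on polygons and `decompose_area_change()` inverts it,
$s=\sqrt{\zeta}$. The shear content is deliberately *not* estimated from
images: local shape descriptors (elongation, circularity, convexity,
compactness, solidity) turn out to be far more variable than the global
area, so the package quantifies only the compression factor and reports
shear as unresolved.

## The three state-equation families

Write $\hat p = (p - p_0)/p_\mathrm{ref}$ for the nondimensional
overpressure. The package defaults to $p_\mathrm{ref} = p_0$ (the baseline,
101.325 kPa unless set otherwise); some pressure scale is required for
dimensional consistency of the exponents below, and this choice makes the
initial area modulus exactly one.

**Exponential family.** Define the area modulus
$B = (1/A)\,\partial A/\partial\hat p$ and let it vary linearly,
$B(\hat p)=B_0+B'\hat p$ with $B_0=1$. Integration gives

$$A(p) = A_0 \exp\!\left(B_0\hat p + \tfrac12 B'\hat p^2\right),$$

on the admissible domain $B_0 + B'\hat p > 0$ (positive modulus, so
$dA/dp>0$ throughout). Differentiating twice,

$$\frac{\partial^2 A}{\partial \hat p^2}
  = A_0\,\bigl(B' + (B_0+B'\hat p)^2\bigr)\,e^{B_0\hat p + B'\hat p^2/2}.$$

Note the *additive* $B'$ term: dropping it (i.e. writing the curvature as
proportional to $B'(1+B'\hat p)$ alone) misplaces the inflection point.
The package implements the calculus-consistent form above and verifies it
against Richardson-extrapolated central differences in the test suite. For
$B'<0$ the curvature changes sign exactly once, at

$$(B_0+B'\hat p_k)^2 = -B' \quad\Longrightarrow\quad
  \hat p_k = \frac{-B_0+\sqrt{-B'}}{B'},$$

the maximum-deformation-rate point $(p_k, A_k)$; for $B'\ge 0$ the curve is
convex everywhere and `find_inflection()` truthfully reports absence.

**Logarithmic-integral family.** If instead the area properties vary
continuously with pressure, the ratio hypothesis
$\zeta = \exp\bigl(\alpha_1 (\partial A/\partial p)(p-p_0)/A_0\bigr)$
integrates to

$$\frac{p-p_0}{p_0} = \exp\bigl(\alpha_1\,\mathrm{li}(A/A_0)\bigr),
\qquad
\mathrm{li}(x) = \int_{1+\epsilon}^{x} \frac{du}{\ln u}.$$

The integrand diverges at $A/A_0=1$, so the integral is regularized with a
finite lower limit $1+\epsilon$; $\epsilon$ (default $10^{-6}$) is a
reported model constant, not a numerical fudge -- every li-family result is
conditional on it. Evaluation goes through the exponential integral
($\mathrm{li}(x)=\mathrm{Ei}(\ln x)$, via **pracma**); the independent
check in the tests uses adaptive quadrature. Two structural facts are worth
recording: the model gives $p \to 2p_0$ as $A \to A_0(1+\epsilon)^+$ (it
does not anchor at $(A_0, p_0)$), and for $0<\alpha_1<1$ the curvature of
$A(p)$ changes sign where $A/A_0 = 1/\alpha_1$, which the located
inflection reproduces together with the balance diagnostic
$\beta\,\alpha_1 A/A_0 = 1$. With the default $\epsilon=10^{-6}$ the
regularization offset pushes that point to very high pressures; a moderate
$\epsilon$ (e.g. $10^{-2}$) brings it into the experimental window.

**Tait-like family.** With a constant area modulus plus a correction one
obtains a power law structurally identical to the Tait equation of state
for liquids,

$$p = \alpha_3\,p_0\,(A/A_0)^{\kappa} + p_0 .$$

The exponent is written $\kappa$ because the underlying correction factor
and the dimensionless difference factor enter only through their product
$\alpha_2(1+\gamma)$; they are not separately identifiable and the package
never reports them individually. The forward/inverse pair is algebraic and
exact. Two consequences of the fixed exponent: at $A=A_0$ the model gives
$p = p_0(1+\alpha_3)$, not $p_0$ (the same anchoring caveat as the li
family), and the curvature $\propto \frac1\kappa(\frac1\kappa-1)$ never
changes sign, so the Tait family has no interior inflection -- the package
reports this honestly rather than forcing one.

## Discrete trajectories and loading-rate continuation

Because the cell is much smaller than the shock thickness, loading is
modelled as a chain of equilibrium states at equal pressure increments
(constant $\dot p$). `isobaric_trajectory()` records the states and the
step ratios $\zeta_i = A_{i+1}/A_i$, which telescope to
$\prod_i\zeta_i = A_n/A_0$.

`loading_rate_continuation()` holds the final state fixed and varies the
number of steps: few, coarse steps emulate high loading rates, many fine
steps low rates. For each discretization it reports the
*maximum-deformation-rate step*. A note on the definition: the raw step
ratio $\zeta_i$ is maximal at the first step for any log-concave $A(p)$, so
it cannot serve as the locus of maximum deformation rate; the package uses
the step with the largest area increment $A_{i+1}-A_i$, whose continuous
limit is $\arg\max dA/dp$ -- exactly the inflection point. Coarser
discretizations shift this locus monotonically toward larger areas (the
high-rate picture), and the fine-step limit converges to
`find_inflection()`'s $(p_k, A_k)$; both properties are asserted in the
tests.

## Two-compartment refinement

The two-stage picture -- early fluid-like cytoplasm spreading, later
nucleus-limited expansion -- is captured by splitting the area response:

$$\frac{\partial A_\mathrm{cell}}{\partial p}
 = \frac{A_\mathrm{cell}-A_\mathrm{core}}{A_\mathrm{cell}}
   \frac{\partial A_\mathrm{cyto}}{\partial p}
 + C\,\frac{A_\mathrm{core}}{A_\mathrm{cell}}
   \left(\frac{\partial A_\mathrm{core}}{\partial p}
       + p\,\frac{\partial^2 A_\mathrm{core}}{\partial p^2}\right),$$

with $\partial^2 A_\mathrm{core}/\partial p^2 < 0$ (pore collapse makes the
nucleus progressively stiffer). The default core response is a concave
quadratic (`quadratic_core()`), the paper-level specification being only
the concavity sign. The ODE is integrated with a fixed-step classical RK4
scheme (**deSolve**), with the cytoplasm and core contributions accumulated
as separate states so that the conservation identity
$\Delta A_\mathrm{cell} = \Delta A_\mathrm{cyto} + \Delta A_\mathrm{core}$
is verified at every grid point (it holds to integrator precision, reported
as an attribute). The concavity requirement is enforced only when the core
term is active ($C \ne 0$); with $C=0$ a constant core is a legitimate
degenerate case used by the tests.

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are set once and
not tuned per analysis.

* **Population** (`population_spec()`): 198 cells; initial area
  $\mathcal N(550, 150^2)$ µm², perimeter $\mathcal N(100, 18^2)$ µm, both
  truncated at zero by resampling (truncation is a >3σ event, so the
  Shapiro-Wilk checks are unaffected); inclination angle uniform on
  [0°, 180°). The area/perimeter scale is typical of well-spread adherent
  macrophage-like cells; the distributions are deliberately independent,
  since population heterogeneity masks the geometric perimeter-area link.
* **Pressure levels**: fifteen levels at centres 478–3178 kPa with the
  tabulated dispersions; level sizes are 13 and 9 for the two highest
  levels (the study reports those counts) and the remaining 176 cells are
  split over the lower thirteen levels as seven groups of 14 and six of 13.
  Draws are truncated to the corrected sensor span 156.48–3603.85 kPa.
* **Response**: Tait family with $\kappa = 1.5$, $\alpha_3 = 0.8$ by
  default (the configuration used throughout the recovery studies).
* **Size coupling** (`size_coupling()`): larger cells deform less at equal
  pressure. The data-level observation is only the sign pattern
  $\partial\zeta/\partial A<0$, $\partial^2\zeta/\partial A^2>0$,
  $\partial\zeta/\partial p\cdot\partial\zeta/\partial A<0$; no functional
  form is given, so the package scales the pressure-scale parameter as
  $\theta(A_0)=\theta_\mathrm{ref}(A_\mathrm{ref}/A_0)^{\eta}$ with
  $\eta=-0.5$ ($\alpha_3$ for Tait, $p_\mathrm{ref}$ for the exponential
  family; the one-parameter li family carries no coupling). This yields a
  power-law decay of $\zeta$ in $A_0$ -- decreasing, convex, and with the
  required competing signs, which `check_surface_signs()` confirms on 100%
  of interior grid cells for the defaults.
* **Fluctuation noise** (`noise_spec()`): transmembrane water exchange
  perturbs the final area multiplicatively -- uniform on $[-a,a]$ under
  stationary fluid, Gaussian with SD $a$ under unidirectional flow. The
  device drives flow in a fixed direction, so the default is Gaussian with
  $a=0.05$; the distribution shapes are specified, the scale is a free
  design constant.
* **Detachment**: a Bernoulli event with logistic probability in the peak
  pressure (defaults give ≈5% of records); a detached record's effective
  maximum pressure is re-read at a random pre-detachment ramp frame,
  emulating the observation rule that truncates at the last adhered frame.
  Detached records are excluded from state-equation fits by default (their
  peak pressure is censored).
* **Rendering** (`render_frames()`): each cell is a star-convex blob
  $r(\varphi)=R\,[1+a_2\cos 2(\varphi-\theta)+\sum_{k=3}^5 a_k
  \cos(k\varphi+\psi_k)]$ whose random harmonics break the perimeter-area
  link; the enclosed area tracks the loading response frame by frame.
  Rasterization uses 3×3 subpixel coverage sampling; intensities are
  background plus coverage-weighted foreground with additive Gaussian
  sensor noise on the 12-bit scale (stored in 16-bit TIFF containers, the
  standard container for 12-bit data). Ground-truth masks (coverage ≥ 0.5)
  and polygons (rescaled so their shoelace area equals the intended area
  exactly) are emitted alongside.

What the generator does **not** emulate: real bright-field texture,
debris and illumination gradients; shear-induced shape distortion within
the frame sequence (areas change, shapes only via the global scale);
viscous time dependence within the ramp; and any absolute calibration of
$\zeta$ against real macrophages -- with the default Tait parameters the
high-pressure ratios (up to ≈13) are larger than a real cell could
sustain. Passing tests therefore demonstrate correctness of the analysis
chain and recoverability of parameters under the assumed noise structure,
not biological realism of the default parameter values.

## Imaging pipeline

Segmentation (`segment_cell()`) follows a conventional route: Otsu
threshold on the normalized frame, morphological opening and closing with a
3-px disc, largest connected component above a 30-px floor (components
covering more than half the canvas, or lacking intensity contrast against
the background, are rejected as threshold noise -- a blank frame yields a
no-cell result, not an error). The subpixel contour is taken by marching
squares (`grDevices::contourLines`) on the intensity image at the level
midway between the component's median foreground and the background, which
lands on the half-coverage isoline of the renderer; on rendered disks the
recovered area is well within the 2% validation tolerance. The
experimental protocol names no specific algorithm, so these stages are
package conventions, validated against ground truth rather than against a
reference implementation.

Descriptors (`measure_shape()`): area by the shoelace formula, perimeter by
edge sums, orientation and elongation ($1-\lambda_{\min}/\lambda_{\max}$)
from the polygon's second-order moments, circularity $4\pi A/P^2$,
compactness defined as its inverse $P^2/(4\pi A)$ (the descriptor list in
the source work carries no formulas; this choice is documented and tested
for internal consistency), convexity $P_\mathrm{hull}/P$ and solidity
$A/A_\mathrm{hull}$. Pixel coordinates are 0-based (row, col) with origin
top-left; contours live in physical µm; angles are measured from the flow
(x) axis in [0°, 180°).

Frame selection (`select_frames()`): the initial state is the last frame
with pressure below baseline + 3 baseline-noise SDs (the frame immediately
before wave arrival); the final state is the frame nearest the pressure
peak, unless a segmentation dropout or a frame-to-frame mask IoU below 0.3
(default; the detachment rule is verbal in the source) signals detachment,
in which case the last pre-detachment frame is used and the effective
maximum pressure is re-read there.

## Grouping and fitting

**Peak-pressure grouping** (`group_by_pressure()`): records are sorted by
peak pressure and accreted greedily into levels under two conditions --
the group's coefficient of variation stays ≤ 5% ("variation below 5%"
read as CV, since the tabulated ± entries are dispersion-like), *and* the
candidate lies within 5% of the running group mean. The second condition
is required, not cosmetic: with the fifteen design centres, fusing the two
levels at 1094 and 1198 kPa gives a combined CV of ≈4.6%, so a pure
CV-greedy pass would deterministically merge adjacent levels no matter how
tight the within-level spread. Groups need more than three members
(min_size = 4); smaller clusters go to the ungrouped residue. Round-trip
recovery of the fifteen levels is exercised with within-level draws at CV
1% (the tabulated dispersions themselves are wider than the 5% rule allows
-- the lowest level's ±24.2 kPa is 5.06% of its centre -- so they describe
the measured groups, not the admissible generative spread; the default
end-to-end pipeline accordingly draws level pressures at CV 1%, while
`generate_dataset()` keeps the tabulated values for faithfulness).

**State-equation fitting** (`fit_state_equation()`): nonlinear least
squares of $\log\zeta$ on the family prediction, with the size-coupling
exponent treated as known design structure. The log scale turns the
multiplicative fluctuation into approximately additive, homoscedastic
noise, so unweighted least squares and Jacobian-based (Gauss-Newton)
standard errors are appropriate; Wald intervals at n ≈ 200 achieve ≈95%
coverage in the Monte-Carlo recovery study. Optimization is
Levenberg-Marquardt (**minpack.lm**) from 16 seeded starts (an analytic
initializer -- log-log regression for Tait -- plus lognormal jitters), the
winner chosen by residual sum of squares; non-convergence is reported, not
raised. `recovery_harness()` wraps the generate→(image→)→fit loop and
tabulates bias, RMSE, median relative error and interval coverage.

**Imaging validation configuration.** The render→segment→measure→fit round
trip uses its own fixed configuration: cells of 280 ± 40 µm² and an
exponential response ($B'=-0.25$, $p_\mathrm{ref}=5000$ kPa, ζ ≤ ≈1.8),
chosen once so that cells remain inside the 120 × 36 µm field of view at
full expansion. Cells that would overflow the canvas are skipped, mirroring
the experimental practice of selecting cells that fit the frame. The
propagated-error comparison between imaging-level and record-level fits
uses the linearized worst-case bound
$|\Delta\theta| \le \delta\,\lVert (J^\top J)^{-1}J^\top\rVert_{1,\mathrm{row}}$
with $\delta$ the largest observed log-ζ discrepancy.

## Problem sizes and numerical choices

Default analyses use n = 198 records; the Monte-Carlo recovery study runs
200 replicates at that size; the distributional validation uses 100
generator seeds; identity and invariance properties are checked over 10^3
random draws; the imaging round trip renders ≈100 cells at two frames
each. Tolerances: state-equation identities to 10^-10 (relative),
derivative-oracle agreement to 10^-5 where the derivative is not passing
through zero, li against quadrature to 10^-8, two-compartment conservation
to integrator precision, segmentation areas to 2%, ζ round trips to 3%.
Inflection searches use analytic roots where available, always confirmed by
bracketed root finding on a central-difference curvature estimate (relative
step 10^-4), ties broken by the smallest pressure. Every stochastic stage
of the pipeline derives its seed deterministically from one global seed, so
runs are reproducible byte for byte.

## Known limitations

The li family is effectively conditional on its regularization constant;
the Tait and li families do not anchor at $(A_0,p_0)$, so their low-pressure
behaviour is extrapolation; shear is modelled but never estimated from
images; detachment pressures are censored rather than modelled; and the
default response parameters are calibration points for the analysis chain,
not measured macrophage properties.
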