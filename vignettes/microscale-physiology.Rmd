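---
title: "Quantitative single-cell physiology at the microscale: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative single-cell physiology at the microscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microphys)
```

## Scope

`microphys` implements a microscale biochemical-engineering workflow for
single microbial cells grown in microfluidic devices: dry mass and dry-mass
density from quantitative phase imaging (QPI), Monod growth kinetics and
substrate-affinity heterogeneity from mother-machine division records,
substrate-to-biomass yields from sealed picoliter batch chambers, carbon
balance closure on a Cmol basis, and an ensemble batch model that propagates
the observed affinity heterogeneity into a population's "physiological
space". Because no public dataset exists for this kind of experiment, the
package ships a first-class synthetic-data generator that emulates the
statistical structure of the measurements; every estimator is validated
against the generator it inverts.

This vignette documents the models, their assumptions, the tunable
parameters, and the places where the design was genuinely open and a choice
had to be made.

## Dry mass from phase images

QPI measures the optical path difference (OPD) accumulated by light crossing
a specimen. For dry matter with specific refraction increment $\alpha$
(mL g$^{-1}$, numerically µm$^3$ pg$^{-1}$), the dry mass inside a region is

$$ m = \frac{\Delta x^2}{\alpha} \sum_{\text{pixels}} \mathrm{OPD}, $$

with $\Delta x$ the pixel size. Dividing by the cell volume gives the
dry-mass density $\rho = m_{cell}/V_{cell}$. Cells are modelled as
spherocylinders — a cylinder of length $l-w$ capped by two hemispheres of
diameter $w$ — with volume
$V = \pi (w/2)^2 (l-w) + \tfrac{4}{3}\pi (w/2)^3$; $l = w$ degenerates to a
sphere, which is also the model for polystyrene calibration beads.

Key parameters, all configurable in `qpi_settings()`:

* `refraction_increment_cell` = 0.18 mL/g, the literature-standard value
  for cellular dry matter. It is a property of the dry matter, not of the
  instrument, but it is the single largest systematic uncertainty in any
  QPI mass measurement, so it is surfaced rather than hard-coded.
* `refraction_increment_bead` = 0.244 mL/g with $n_{bead} = 1.59$ and
  $n_{medium} = 1.333$, so a bead's recovered density should be
  $(1.59-1.333)/0.244 \approx 1.053$ pg/µm$^3$ — the control that anchors
  the whole mass pipeline.
* `segmentation_threshold` = 0.005 µm OPD with `min_area_px` = 10: five
  standard deviations above the default rendering noise (0.001 µm), so
  spurious components are effectively impossible while the faintest cells
  of the density envelope (0.13 pg/µm$^3$, peak OPD ≈ 0.023 µm) are still
  detected.

### Morphometrics by method of moments

The obvious way to extract $l$ and $w$ — extents of the binary mask along
its principal axes — fails quantitatively at the scale of a bacterium
(width ≈ 22 px at 0.045 µm/px): mask extents are quantized to whole pixels,
and a 1-px width error is a ~9% volume error. `measure_cells()` therefore
inverts the OPD-weighted second moments instead. Weighting each pixel by
its OPD is equivalent to weighting by the projected thickness of the 3-D
body, for which a spherocylinder has closed forms: with cylinder
half-length $a$, radius $r$, cylinder volume $V_c = 2\pi r^2 a$ and cap
volume $V_s = \tfrac{4}{3}\pi r^3$,

$$ \mathrm{Var}_\perp = r^2\,\frac{V_c/4 + V_s/5}{V_c+V_s}, \qquad
   \mathrm{Var}_\parallel = \frac{\tfrac{2}{3}\pi r^2 a^3 +
   2\pi\left(\tfrac{2}{3}a^2r^3 + \tfrac{1}{2}ar^4 +
   \tfrac{2}{15}r^5\right)}{V_c+V_s}. $$

The two measured eigenvalues of the weighted covariance matrix (after
subtracting the uniform pixel-integration variance $\Delta x^2/12$) are
inverted for $(r, a)$ by alternating one-dimensional root finding; both
equations are monotone in their unknown, so the iteration converges in a
few steps. At $a=0$ both variances reduce to the sphere value $r^2/5$,
which is the degenerate branch used for beads. The estimator is
threshold-free, sub-pixel, and unbiased under zero-mean noise; on rendered
cells it recovers density to well under 1%, versus ~5–10% for mask extents.

Mass integration uses the detection mask dilated by 5 px so the faint rim
below the threshold is included; the residual scalar background is
estimated as the mean of all off-object pixels first (a low-percentile
scalar, as in `subtract_background()`, is biased by $-1.64\sigma$ under
Gaussian noise), so the dilation ring contributes only zero-mean noise.

## Growth kinetics from division records

For each mother-machine lineage, doubling times are the differences of
consecutive division timestamps, discarding the first interval (the age of
the initially observed cell is unknown). Division detection is
frame-limited; two divisions on consecutive frames indicate a segmentation
glitch rather than a real doubling, so intervals of at most one frame get
weight 0. Per glucose level the doubling time is summarized by the
geometric mean of the admissible intervals — robust to multiplicative
outliers — and the growth rate is $\mu = \ln 2 / t_{d,gm}$. Heterogeneity
is the weighted standard deviation of the per-event rates with a
$(\sum w - 1)$ denominator. Levels are classified `valid` (a single lineage
with ≥ 50 events), `pooled` (≥ 4 generations summed across lineages), or
`no_growth` (< 4 generations); no-growth levels are excluded from fitting.

The Monod model $\mu(S) = \mu_{max} S/(K_S+S)$ is a sigmoid on the
$\log_{10} S$ axis. `fit_monod()` operationalizes the "graphical sigmoidal
estimation" as nonlinear least squares (Levenberg–Marquardt) of that
sigmoid, reading $K_S$ from the fitted half-maximum abscissa — equivalent
to the graphical half-point reading, but reproducible. Three variants are
fitted: the mean curve, and *upper*/*lower boundary* curves through
$\mu_{gm} + \sigma$ and $\max(\mu_{gm} - \sigma, 0)$. How boundary curves
should be constructed was an open design point; fitting the ±SD curves is
the simplest construction that reproduces the characteristic inversion in
which the upper boundary (faster growth) carries the *smaller* $K_S$.

Per-cell affinities are obtained by inverting Monod per admissible
division event, $K_S = S(\mu_{max}/\mu_{cell} - 1)$; cells at or above
$\mu_{max}$ carry no affinity information and are skipped (and counted).
The inversion is most informative for $S$ near $K_S$ — at saturating $S$
the estimate is ill-conditioned, which is inherent to the model, not to
the implementation.

## Yields and the Cmol carbon balance

In a sealed chamber of known total volume (default 606 pL) the initial
substrate mass is exactly $S_0 = c_0 V$ (1 g/L ≡ 1 pg/pL). Monolayer
growth makes total biomass observable as projected colony area × chamber
height × dry-mass density, and the yield is
$Y_{X,S} = (m_{end} - m_0)/S_0$. The final biomass is averaged over the
last five stationary-phase frames to suppress frame-level segmentation
noise. Chambers whose yield implies more carbon in biomass than was
supplied, or that start from fewer than a configurable number of cells,
are *flagged* excluded rather than silently dropped.

With by-products unmeasurable at this scale, the product pool $P$ lumps
everything that is neither substrate nor biomass (CO$_2$, organic acids),
and carbon conservation closes the balance:

$$ q_S^{Cmol} = \frac{\mu}{Y_{X,S} M_S}, \quad
   r_P = q_S^{Cmol} - \frac{\mu}{M_X}, \quad
   Y_{P,S} = 1 - Y_{X,S}\frac{M_S}{M_X}, $$

with Cmol masses $M_X$ = 24.63 g/Cmol (biomass CH$_{1.8}$O$_{0.5}$N$_{0.2}$,
the standard elemental composition for enteric bacteria) and $M_S$ = 30.03
g/Cmol (glucose, CH$_2$O). The exact composition is strain- and
condition-dependent and not universally agreed, so both masses are
configurable and echoed in every report. Maintenance energy is not
modelled; the closure attributes all non-biomass carbon to $P$.

## The dynamic ensemble model

The batch material balance
$dX/dt = \mu(S)X$, $dS/dt = -\mu(S)X/Y_{X,S}$, $dP/dt = r_P(S)X$
is integrated with a fixed-step classical 4th-order scheme (default
$dt = 0.001$ h). Because $dS$ and $dP$ are proportional to $dX$, the
solver integrates only $X$ and recovers $S$ and $P$ algebraically from the
balance — total carbon $X/M_X + S/M_S + P$ is then conserved to machine
precision *by construction*, and the conservation test verifies it
numerically rather than trusting it. Substrate is floored at zero at
exhaustion, after which $\mu = 0$. A step producing more than 10% relative
biomass change raises an error advising a smaller step; halving the
default step changes final states by less than $10^{-4}$ relative.

Ensembles draw one $K_S$ per member from a normal distribution truncated
at zero (exact rejection sampling, seeded) — either specified directly or
taken from an empirical `ks_distribution()` — while $\mu_{max}$ and the
stoichiometry are shared. Only the affinity varies because the observed
heterogeneity is characterized as an affinity distribution; whether
$\mu_{max}$ also varies per cell is unknown, and adding a second
heterogeneous parameter without data to constrain it would only inflate
the simulated space. `phenotype_space_summary()` reduces an ensemble to
time-resolved min/5%/median/95%/max envelopes per state variable. The
pipeline stage uses 100 members at $dt = 0.005$ h, which resolves the
envelopes while keeping a full synthetic run inside interactive time.

## The synthetic-data generator

The generator is the package's substitute for the microfluidic
experiments, and its defaults *are* the study conditions:

* Monod kinetics with $\mu_{max} = 0.66$ h$^{-1}$ and mean affinity
  $K_S = 486$ µg/L; per-cell affinity drawn from a normal truncated at
  zero with CV $= 234/486 \approx 0.48$ (the reported population SD).
* Doubling-time observation noise: multiplicative lognormal with CV 0.4
  (~±40% heterogeneity) and **unit median**. The location of the lognormal
  was an open choice; a unit-*mean* multiplier has geometric mean
  $e^{-\sigma^2/2}$, which would bias every geometric-mean growth rate —
  and hence $\mu_{max}$ — upward by ~8% at CV 0.4. Unit median keeps the
  generator/estimator consistency loop centred, which is the property the
  invariant tests assert.
* Eight log-spaced glucose levels from $10^{-5}$ to 10 g/L; three mother
  lineages of 60 division events per level (a single selected mother line
  guarantees ≥ 50 events; several chambers are tracked per condition);
  5-min frames with division timestamps rounded to the frame grid; 1% of
  events followed by a spurious one-frame "consecutive division" artifact
  so the weight-0 rule is exercised.
* Phase images: ideal projection of 3-D spherocylinders/spheres (chord
  length through the body per pixel centre) times $\rho\alpha$, plus
  additive Gaussian background noise; no diffraction, halo, or shot
  noise. Cell densities span the observed 0.13–0.28 pg/µm$^3$ envelope.
* Picoliter batches: Monod growth on the instantaneous concentration
  $S = s/V$ in a 606 pL reactor, observed every 20 min as projected area
  with 2% lognormal segmentation noise, plus ten stationary-phase frames
  after exhaustion (yields are measured at stationary phase, so the
  plateau must be observable).

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate on real data: optical artifacts (halo, diffraction,
defocus), segmentation and tracking errors beyond the two simple noise
models, asymmetric division and age structure, nutrient gradients and
mechanical crowding inside colonies, glucose adsorption/evaporation in the
chambers, and any real uncertainty in $\alpha$. Estimator accuracies
reported here are accuracies *under the model*.

## Numerical choices and degenerate inputs

* Seeds: every stochastic entry point takes an explicit seed; independent
  pipeline stages derive distinct sub-seeds from the one user seed so that
  streams do not collide. Same seed ⇒ bit-identical outputs.
* Truncated-normal draws use rejection sampling (exact distribution; a
  `pmax(0, ...)` clip would pile mass at zero) with a retry limit that
  raises an error for absurd parameterizations.
* `fit_monod` starting values: $\mu_{max}$ from the largest observed rate,
  $K_S$ from log-linear interpolation of the half-maximum crossing; the
  optimizer is bounded below at $10^{-9}$/$10^{-12}$ to keep parameters
  positive. Non-convergence raises an error carrying the point count and
  rate range; an all-saturating dataset (minimum $S$ > 100 × fitted
  $K_S$) fits but warns that $K_S$ is poorly identified.
* Quantization ties: two divisions rounded onto one frame are pushed one
  frame apart (timestamps must be strictly increasing); the resulting
  one-frame interval is then down-weighted downstream, exactly as a real
  frame-limited detector would behave.
* Degenerate masks (< 4 px or non-positive total weight) fall back to
  single-pixel geometry rather than erroring, so one broken object cannot
  abort a whole-image measurement; empty masks in `integrate_dry_mass`
  return mass 0 with a warning.
* Problem sizes in the test suite and pipeline (events per level, ensemble
  size, image sizes) are chosen so a full synthetic run completes in
  interactive time; all recovery tolerances were set from the estimators'
  behavior under the study conditions, not tightened to the minimum that
  passes.

## Known limitations

* The moment-based morphometrics assume an isolated, non-overlapping,
  in-focus spherocylinder; touching cells are segmented as one object.
* $K_S$ inversion near saturation is ill-conditioned (a model property);
  the affinity distribution should be measured near the half-saturation
  regime.
* The ensemble model propagates parameter heterogeneity only; it contains
  no division-level stochasticity, no lag phase, and no product
  inhibition.
* The Cmol closure depends linearly on the assumed biomass composition;
  reported $Y_{P,S}$ inherits that uncertainty in full.
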