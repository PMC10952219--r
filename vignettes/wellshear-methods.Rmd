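---
title: "Shear-stress metrics for swirling-well flow: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-stress metrics for swirling-well flow: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellshear)
```

## The system

Endothelial cells are commonly exposed to flow by culturing them on the
base of a circular well that rides on an orbital shaker ("swirling
well"). The orbit drives a wave that rotates around the well, and the
wall shear stress (WSS) vector at each point of the base varies in
magnitude and direction over the cycle: nearly uniform rotation
(multidirectional flow) at the centre, nearly uniaxial back-and-forth
flow at the edge. Geometric modifications change this picture: a
cylinder attached to the base confines flow to an annular channel and
suppresses radial components; a cylinder suspended a millimetre or two
above the base makes the flow under it almost purely multidirectional;
tilting the well breaks the azimuthal symmetry altogether.

`wellshear` implements the analysis layer of this kind of study: the
dimensionless characterization of a well/orbit/fluid configuration, the
standard WSS metrics computed from vector time series, polar-locus shape
analysis, and field-level aggregation into radial profiles and 2-D maps.
It deliberately does **not** solve the flow: a synthetic generator
reproduces the geometric and statistical structure of the flow regimes
so that every downstream step can be exercised and verified against
analytic limits.

## Dimensionless characterization

A configuration is summarized by six groups, computed by
`dimensionless_groups()`:

$$E = \frac{a}{L},\quad
  F = \frac{a\omega^2}{g},\quad
  \Gamma = \frac{d}{L},\quad
  \mathrm{Re} = \frac{L^2\omega}{\nu},\quad
  \mathrm{Bo} = \frac{(\rho_l-\rho_a)\,g\,(2L)^2}{\sigma},\quad
  \mathrm{We} = \frac{\rho_l U^2 (2L)}{\sigma},$$

with orbital radius $a$, angular rate $\omega$, mean depth $d$, gravity
$g$, liquid/air densities $\rho_l,\rho_a$, surface tension $\sigma$,
kinematic viscosity $\nu$, and $U = R\omega$ the linear velocity at the
well edge. The characteristic length $L$ is the well radius $R$ for a
plain well; when a central cylinder is present the flow lives in an
annular channel and $L$ is the channel width $R_\mathrm{well} -
R_\mathrm{cyl}$ (`characteristic_length()`). All of $E$, $\Gamma$ and
$\mathrm{Re}$ use the same substituted length, so the suspended-cylinder
variants are simultaneously high-eccentricity, high-shallowness,
low-Reynolds configurations even though the physical well is unchanged.

Three conventions deserve a note:

* **Forcing.** $F$ is the amplitude of the orbital acceleration
  $a\omega^2$ normalized by gravity — the ratio of the driving body
  force to the restoring one. For the standard 150 rpm, 5 mm-orbit
  configuration $F = 0.13$.
* **Viscosity.** $\nu$ defaults to $\mu/\rho_l$ ($0.78\times10^{-3}$ Pa·s
  over 1003 kg/m³ $\approx 7.78\times10^{-7}$ m²/s). Quoting the rounded
  $0.78\times10^{-6}$ m²/s instead would shift Re for the standard well
  from 2466 to 2459; the package always uses $\mu/\rho$ unless an
  explicit kinematic override is configured, which is how
  dextran-thickened media (2.2–4.0 mm²/s) are represented.
* **Surface tension.** Defaults are 0.072 N/m for plain and tilted wells
  (water-like medium) and 0.047 N/m for cylinder variants
  (serum-supplemented medium); both are overridable. Reference values
  quoted in the literature for cylinder configurations appear to mix the
  two conventions between Bo and We; `wellshear` always computes both
  groups from the single configured $\sigma$, so with $\sigma = 0.047$
  the central-cylinder variant gives Bo = 42 and We = 9 (We = 6 would
  require $\sigma = 0.072$). The discrepancy is a property of the quoted
  values, not of the formulas, and is left visible rather than patched.

`characterize_row()` rounds for reporting the way these tables are
customarily printed: two decimals for $E$, $F$, $\Gamma$, nearest
integer for Re, Bo, We.

## The seven WSS metrics and four directions

For one point, the input is one cycle of uniformly sampled instantaneous
stress vectors $\vec\tau(t_k)$, $k = 1,\dots,n$ (class `wss_series`,
built directly or by the generator; at least 8 samples, 360 per cycle by
default). With $T$ the period and $\vec n$ the wall normal:

$$\mathrm{TAWSS} = \frac1T\int_0^T |\vec\tau|\,dt, \qquad
  \mathrm{MagMeanWSS} = \left|\frac1T\int_0^T \vec\tau\,dt\right|, \qquad
  \mathrm{OSI} = \frac12\left(1 - \frac{\mathrm{MagMeanWSS}}{\mathrm{TAWSS}}\right),$$

$$\mathrm{transWSS} = \frac1T\int_0^T
  \left|\vec\tau\cdot\left(\vec n\times\frac{\vec\tau_\mathrm{mean}}{|\vec\tau_\mathrm{mean}|}\right)\right| dt,
  \qquad
  \mathrm{CFI} = \frac1T\int_0^T
  \left|\frac{\vec\tau}{|\vec\tau|}\cdot\left(\vec n\times\frac{\vec\tau_\mathrm{mean}}{|\vec\tau_\mathrm{mean}|}\right)\right| dt,$$

and the minimized variants transWSS~min~ and CFI~min~ replace the
mean-vector reference by the in-plane axis $(\cos\phi,\sin\phi,0)$ that
minimizes the same cycle average over $\phi$. The integrands carry
absolute values: without them the signed cross components of any
symmetric locus cancel to zero and the circular-locus limit $2/\pi$
below would be unreachable. Analytic limits, used as test oracles:

* a constant-magnitude rotating (circular) locus has OSI = 0.5 (its
  ceiling), CFI~min~ = $2/\pi \approx 0.64$, and
  transWSS~min~ = $(2/\pi)\,$TAWSS;
* purely uniaxial oscillation has OSI = 0.5 but CFI~min~ = 0 — the two
  families of metrics separate oscillation from true multidirectionality;
* steady flow zeroes every multidirectionality metric.

CFI can exceed $2/\pi$ when large opposed vectors leave a small mean
nearly perpendicular to them; OSI can never exceed 0.5.

**Quadrature.** Samples are uniform over a closed cycle, so every cycle
average is the plain arithmetic mean (the trapezoidal rule on a closed
periodic grid reduces to it). For smooth loci doubling the sampling
changes metrics by well under $10^{-4}$ relative; integrands with kinks
(the absolute values) converge quadratically.

**Undefined metrics are explicit.** OSI requires TAWSS > 0; transWSS and
CFI require a usable mean direction, which a perfectly symmetric locus
does not have (the package treats $|\vec\tau_\mathrm{mean}| \le
10^{-10}\,\mathrm{TAWSS}$ as degenerate). These conditions raise classed
errors from the individual functions and surface as `NA` plus a reason
code in `compute_metric_set()` — never as a silent 0, which would mean
the physical opposite. Zero-magnitude samples are excluded from the
CFI-type averages (their direction is undefined) and counted.

**The axis minimization.** The objective
$f(\phi) = \overline{|b\cos\phi - a\sin\phi|}$ (with $(a,b)$ the
radial/tangential components, normalized or not) has period $\pi$ and is
piecewise smooth with kinks where an individual sample's cross component
changes sign — at the sample's own direction angle. Its minimum is
either such a kink (exactly zero for steady or perfectly uniaxial flow)
or an interior smooth point. The implementation therefore evaluates
$f$ at all sample-direction angles *exactly*, scans a quarter-degree
grid, and refines every competitive local basin (up to eight within 5 %
of the grid range) with `stats::optimize`. Refining only the single
best grid point is not enough: near-tied basins would make the result
depend on how the grid happens to align with the locus, breaking
rotation equivariance at the $10^{-5}$ level. When the total variation
of $f$ does not exceed the sampling quadrature ripple
($\tfrac12(\pi/n)^2$ relative), the axis is physically indeterminate —
a uniformly sampled circular locus — and is reported as `NA` with a
`flat` flag rather than as an arbitrary angle.

**Modal direction.** Instantaneous directions (full $[0,2\pi)$, not the
$\pi$-periodic axes) are binned into 18 left-closed 20° bins; the centre
of the most populated bin is reported, ties broken toward the lower bin
and flagged. For a uniformly rotating locus every bin ties — the modal
direction is meaningless there, and the flag says so.

## Polar loci, ellipse fits and the Shape Index

`locus_from_series()` projects a series into the coordinates used for
polar plots: tangential versus radial components with the signs chosen
so that negative radial points toward the well centre and negative
tangential points along the wave-travel direction. The shape of the
closed curve traced by the vector tip summarizes multidirectionality,
quantified by fitting an ellipse and computing the Shape Index

$$\mathrm{SI} = \frac{4\pi A}{P^2},$$

1 for a circle and 0 for a straight line. The fit is the numerically
stable direct least-squares conic fit constrained to an ellipse
(quadratic/linear block split with the ellipse constraint imposed on a
3×3 eigenproblem), after centring the points; it needs no
initialization and recovers noiseless ellipse parameters to $10^{-6}$
or better. The perimeter uses Ramanujan's second approximation —
relative error below $10^{-9}$ up to roughly 2:1 aspect ratio and below
$10^{-4}$ even at 20:1, bounded in the tests against numerical
quadrature of the arc-length integral.

Highly elongated loci defeat ellipse-specific fitting (the constrained
eigenproblem loses its admissible solution). Rather than failing — the
historical behaviour of such algorithms — `fit_ellipse()` returns the
principal-component segment as a zero-minor-axis ellipse with
`degenerate = TRUE`, and `shape_index()` maps it to 0. The flag
preserves the information that no true ellipse existed.

## The synthetic flow generator

`make_locus()` produces one point's series from a `locus_spec`, in four
regimes that span what the real flows produce: `circular` (constant
rate, constant magnitude), `elliptic` (axis-aligned, optionally
forward-biased), `uniaxial_oscillatory`, and `steady`. Choices:

* **Period and sampling.** 0.4 s (150 rpm) and 360 samples per cycle by
  default. Solver extractions of this kind of flow typically yield
  $\sim$80 samples per cycle; 360 keeps quadrature error comfortably
  below the test tolerances while remaining configurable.
* **Forward bias.** The time warp $\psi(u) = 2\pi u + \alpha\sin(2\pi u)$
  ($0 \le \alpha < 1$, monotone) slows the phase near the
  negative-tangential part of the cycle, so the vector spends more time
  pointing along the wave direction — the behaviour seen at the well
  edge. The bias magnitude is a free parameter: no quantitative value is
  established for real wells.
* **Noise.** Optional per-component Gaussian noise, seeded and
  reproducible, applied without disturbing the caller's RNG stream.
  Default 0 so analytic targets are exact.
* **$\tau_z = 0$** everywhere: the base is flat. The metrics still
  consume all three components.

`make_disc_field()` builds a rotating-wave field: the series at
$(r,\theta)$ is the series at $(r,0)$ with its time origin shifted by
$\theta/\omega$ and its frame rotated to the local radial/tangential
directions — exact by construction, which is what makes the
azimuthal-symmetry assertions on radial profiles meaningful.
`make_tilted_field()` emulates tilt-broken symmetry by scaling stress
amplitudes with $1 + m\cos(\theta - \theta_0)$; depth $m = 0$ reduces
identically to the symmetric field. Scaling leaves OSI/CFI-type metrics
untouched and moves the TAWSS maximum to $\theta_0$, reproducing the
qualitative signature of a tilted well (dimensional metrics peak near
the high point, dimensionless ones do not follow).

The bundled `scenario_profile()` radial families ("control_like",
"sc_like", "cc_like") encode the regime layout of the standard well,
the suspended-cylinder well and the attached-cylinder channel, with
representative tenths-of-Pa amplitudes. Their near-circular regimes
carry a 2 % steady tangential bias in the wave direction: real
rotating-wave loci are only approximately centred, and a perfectly
symmetric locus has no mean direction, leaving transWSS and CFI
undefined. The bias keeps them defined (CFI within 0.01 of $2/\pi$,
OSI within 0.01 of 0.5) without changing any qualitative pattern.

What the generator does **not** emulate: free-surface shape and wave
breaking, Reynolds-number dependence, boundary-layer structure, actual
stress magnitudes, or any coupling between radius and regime beyond
what the user's radial profile encodes. Tests passing on synthetic
fields therefore validate the *analysis* — metric definitions, shape
fitting, aggregation, symmetry handling — not any claim about a
particular physical well.

## Field pipeline

Fields travel as a plain CSV dialect (`point_id`, `x_m`, `y_m`,
`time_s`, `tau_x_pa`, `tau_y_pa`, `tau_z_pa`), written losslessly and
validated on read: missing columns, ragged time axes and non-uniform
sampling (beyond $10^{-6}$ of the period) are reported as errors naming
the offending point. Inputs spanning several cycles are truncated to the
final cycle, the convention for reporting converged periodic flow; the
truncation is logged. An optional decimation flag mirrors every-n-th
step extraction. VTK series input is not supported — the CSV dialect is
the interchange format.

Coordinates put the origin at the well centre with $\theta$ measured
counter-clockwise and the tilt high point at $\theta = 0$ by default,
so map orientation is unambiguous. Radial profiles use half-open
equal-width bins (50 over $[0, R]$ by default, configurable); empty bins
are reported with zero occupancy, never interpolated, which makes a
masked cylinder footprint visible rather than smoothed over. Per-bin
standard deviations accompany every mean so the rotating-wave symmetry
(zero azimuthal dispersion up to round-off) can be asserted.
`run_pipeline()` orchestrates the whole chain from a YAML configuration
and collects a structured log of every silent-looking decision (cycle
truncation, excluded zero-magnitude samples, degenerate ellipse fits)
precisely because such fallbacks would otherwise corrupt downstream
interpretation.

## Problem sizes and verification

The examples and tests run at deliberately modest sizes — fields of
10–20 radii × 4–8 azimuths, 90–360 samples per cycle — because every
property being checked (analytic limits, symmetry, equivariance,
oracle agreement) is already decisive there. The randomized suites run
100 seeds per property: metric inequality chain, scale
invariance/linearity, rotation equivariance, agreement of the axis
minimization with an exhaustive 0.05° grid, ellipse parameter recovery,
and azimuthal-symmetry consistency of radial profiles. Minimized
metrics are located numerically, so inequality and invariance
assertions carry $10^{-8}$-level slack; values on near-flat objectives
are accurate to about $10^{-6}$ relative.

## Known limitations

* The dimensionless characterization trusts its inputs; it does not
  classify flow stability or resonance regimes.
* The asymmetry parameter of the generator is qualitative, not
  calibrated to measured edge loci.
* CFI-type metrics on loci with a genuinely vanishing mean are
  undefined by construction; analyses of perfectly symmetric synthetic
  fields should use OSI, CFI~min~ and transWSS~min~ instead, or add the
  small bias the bundled scenarios use.
* The tilt emulation is a pure amplitude modulation: it reproduces
  where dimensional metrics peak, not the full asymmetric physics of a
  tilted free surface.
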