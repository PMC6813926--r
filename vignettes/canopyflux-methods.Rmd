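---
title: "Leaf-resolving canopy biophysics with canopyflux: models, assumptions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf-resolving canopy biophysics with canopyflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopyflux` simulates the biophysics of a plant canopy one leaf at a time:
every leaf is an explicit geometric element that intercepts its own light,
solves its own energy balance, and runs its own stomatal and photosynthetic
machinery. The package exists to study how strongly skewed the resulting
leaf populations are — which small fraction of leaves does most of the
canopy's light absorption, transpiration and carbon gain — and how that
skew differs between an isolated tree and a closed canopy.

This vignette explains the models, the choices made where the design was
genuinely open, and what the synthetic test conditions do and do not show
about real canopies. No numbers are quoted here that the test suite or the
acceptance script do not compute themselves.

## Geometry and data

The `cf_context` is a registry of primitives (triangles, rectangular
patches, voxels) in a right-handed frame with z up, x east, y north;
azimuths are measured clockwise from north. Patches can carry boolean
occupancy masks (rasterized from an image alpha channel if desired): masked
cells carry no area and rays pass through them. Per-primitive and global
named data behave like a typed key-value store; weather series attached to
the context are linearly interpolated in time and queries outside the record
span are errors rather than extrapolations. UUIDs are monotonically
increasing integers and never recycled, which keeps every run replayable.

ASCII PLY and Wavefront OBJ meshes are read and written directly (polygon
faces are fan-triangulated); the XML configuration dialect (`<patch>`,
`<triangle>`, `<band>`, `<physiology>`, `<weather>`, `<simulation>`) is this
package's own documented schema and is not claimed compatible with any other
tool's.

## Radiation transport

Radiation is traced in reverse: rays start at the receiving surface and
sample where its radiation comes from. Three source types are supported per
waveband — collimated (direct solar), isotropic diffuse sky, and thermal
emission — plus an iterative redistribution of reflected/transmitted
(scattered) flux. All planar primitives can absorb on both faces; fluxes
are always reported per one-sided area.

* **Collimated.** Each primitive launches stratified, jittered rays toward
  the sun; the unoccluded fraction multiplies
  `flux * |cos(incidence)|`. Internally the scene is projected onto the
  plane normal to the beam once per time step and rasterized into a 2D grid
  with depth-sorted candidate lists, which makes the per-step cost linear in
  rays with small constants.
* **Diffuse and exchange.** Cosine-weighted hemisphere rays from each face
  record which primitive (or the sky) every incoming direction sees. The
  aggregated hit counts form a sampled exchange operator reused for three
  purposes: the diffuse sky view factor, the longwave exchange, and the
  scattering redistribution. The operator depends only on geometry, so it
  is built once per static scene and applied as a sparse matrix-vector
  product whenever source radiances change.
* **Emission.** A ray hitting surface j contributes `eps_j sigma T_j^4`
  radiance, a ray escaping upward contributes the downwelling sky longwave.
  Because every sampled ray in a closed isothermal enclosure carries exactly
  the enclosure radiance, the net longwave on every surface is zero for any
  ray count — the estimator cannot create energy from sampling noise. This
  is verified in the tests at 1e2 through 1e4 rays.
* **Scattering.** Each pass re-emits the `rho + tau` share of the incident
  flux bi-Lambertianly from both faces through the exchange operator
  (for equal reflectance and transmittance this is exact; for unequal ones
  it approximates the partition between faces). The default three passes
  leave a geometrically decreasing residual which is reported, so the
  truncation error is measurable rather than silent.

The tracer uses one `splitmix64` random stream per (primitive, kernel)
derived from the master seed: results are bitwise reproducible and
independent of traversal order, and the geometric samples are shared across
wavebands (the hit geometry is band-independent; only the optical
coefficients differ). Periodic lateral boundaries wrap rays around the
domain, standing in for a laterally infinite canopy. Voxels do not
participate in ray tracing.

Known limitations: the diffuse sky is isotropic; there is no penumbra
(point sun); longwave scattering of the `1 - eps` reflected share is
neglected; spherical radiation sources are not implemented.

## Energy balance

Each surface solves

```
R - n eps sigma T_s^4 = c_p g_H (T_s - T_a)
                        + lambda g_M (e_s(T_s) f_s - e_s(T_a) h) / p_atm + Q_other
```

with `c_p = 29.25 J mol-1 K-1`, `lambda = 44000 J mol-1`, Tetens saturation
vapor pressure (`a = 611 Pa`, `b = 17.502`, `c = 240.97 C`), and `n = 2`
for two-sided leaves or `1` for ground. `R` is the absorbed all-wave flux
per one-sided area, including absorbed longwave. The equation is solved by
the secant method from the deterministic bracket `T_a +/- 20 K` to a
residual below 1e-4 W m-2 (default), vectorized over all surfaces at once;
the tests require agreement with a bisection oracle on 1000 random input
vectors. Transpiration is read off the latent term, and negative values
(dew) are flagged rather than clipped. The water-vapor conductance couples
the stomatal and boundary-layer conductances in series with
`g_bw = 1.08 g_H`; the default leaf boundary-layer conductance is the
laminar flat-plate form `0.135 sqrt(u / d)` with wind speed `u` (default
2 m s-1) and leaf dimension `d` (default 0.075 m, the side of a 60 cm^2
leaf).

## Stomatal conductance and photosynthesis

Stomatal conductance is the hyperbolic light/VPD response

```
g_s = E_m (Q + i_0) / (k + b Q + (Q + i_0) D)
```

with the fitted almond coefficients as defaults (`E_m = 20.43 mmol m-2 s-1`,
`i_0 = 38.48 umol m-2 s-1`, `k = 18383 umol m-2 s-1 mmol mol-1`,
`b = 49.68 mmol mol-1`); with these mixed units the value comes out in
mol m-2 s-1, which a dedicated unit test pins down. `Q` is the absorbed PAR
photon flux (4.57 umol J-1) and `D` the leaf-to-air mole-fraction vapor
pressure deficit in mmol mol-1.

C3 photosynthesis follows the standard two-limitation biochemical model:
Rubisco-limited `A_c = V_cmax (C_i - G*) / (C_i + K_c (1 + O / K_o))` and
RuBP-regeneration-limited `A_j = J (C_i - G*) / (4 C_i + 8 G*)`, with
`A = min(A_c, A_j) - R_d`. Kinetic constants (`K_c`, `K_o`, `G*`) and
`V_cmax`, `R_d` scale with leaf temperature by Arrhenius responses
(Bernacchi-style activation energies, all overridable); the electron
transport rate comes from a non-rectangular hyperbola (curvature 0.7,
initial quantum yield `alpha = 0.41`) saturating at
`J_max(T) = J_max25 exp(C_Jmax - dHa_Jmax / (Rg T))`. Note that the default
coefficient pair satisfies `C_Jmax = dHa_Jmax / (Rg * 298.15)` to printed
precision, i.e. the multiplier is ~1 at 25 C; `C_Jmax` is therefore not an
independent degree of freedom, and the fitting routine ties it to
`dHa_Jmax` to keep the model identifiable. TPU limitation and mesophyll
conductance are intentionally out of scope.

The intercellular CO2 balance `A = g_tc (C_a - C_i)` with
`g_tc = (1.6 / g_s + 1.37 / g_bc)^-1` is solved per leaf: each limitation
branch reduces to a quadratic in `C_i`, whose positive root initializes a
damped fixed-point polish (tolerance 0.01 umol mol-1 by default; the
fitting code tightens it to 1e-7 because least-squares jacobians are
computed by finite differences and need a smooth prediction).

**Fitting gas-exchange data.** `fit_gas_exchange()` fits the stomatal
coefficients by Levenberg-Marquardt on the conductance model, then the
photosynthesis parameters on the coupled prediction evaluated at the
observed conductances. With the classic chamber design (a light response at
25 C plus saturating-light points at elevated temperature) every
elevated-temperature observation is Rubisco-limited, so `dHa_Jmax` has no
leverage; the fit is staged — four identifiable parameters first, then an
attempted five-parameter refinement that falls back when the activation
energy is unidentifiable. Simulation-based recovery tests quantify this:
the identifiable parameters come back within a few percent at 5%
measurement noise, while `dHa_Jmax` is only weakly constrained by design.

## Procedural trees and the synthetic canopy

Trees are generated by recursive branching levels: each level prescribes a
child count, a branch angle with a random perturbation magnitude, a length
with jitter, a radius taper, and an upward curvature; azimuths follow a
jittered golden-angle sequence. Terminal twigs carry the leaves — square
patches of constant one-sided area (60 cm^2 by default) with inclinations
drawn by inverse-CDF sampling from a tabulated distribution and uniform
azimuths. Thick members are six-sided tapered tubes;
thin twigs are area-equivalent flat ribbons (a ribbon of width `pi r` has
the same azimuth-averaged projected width as a cylinder of radius `r`),
which keeps the triangle count and ray-tracing cost down without changing
mean interception.

The default "almond-like" tree is roughly 6 m tall with a deep, fairly
narrow crown (about 4 m across and 3.5 m deep) and a crown-level leaf area
density near 3 m^2 m^-3, consistent with a young orchard tree; an earlier,
more diffuse first guess (crown density near 1) was revised because it is
not a plausible orchard crown and produces visibly too-uniform light
distributions. The default
leaf inclination table is spherical, the conventional stand-in when the
real distribution is unknown; a plagiophile alternative
(`plagiophile_leaf_pdf()`, beta-shaped with mean near 32 degrees,
representative of measured orchard canopies) ships alongside it. Under
spherical angles the sunlit leaves spread their absorbed flux uniformly
over the incidence cosine, which mathematically caps the midday top-decile
share near one half at this leaf area index — worth keeping in mind when
comparing against canopies with strongly non-spherical foliage. With
5 x 7 x 12 terminal shoots and 46 leaves per shoot, a 3 x 3 block at 6 m
spacing starts near leaf area index 3.2; pruning the never-profitable
leaves (below) removes roughly a quarter of them. Leaf azimuths, positions
and perturbations are all driven by per-tree streams derived from one
master seed: the same seed reproduces the same canopy bitwise.

`build_homogeneous_slab()` places leaves uniformly at random in a box — the
turbid-medium fixture whose direct transmission has the closed form
`exp(-G L / cos theta)` (G = 0.5 for spherical orientations) used by the
radiation acceptance tests.

## Aggregation statistics

`top_fraction(values, weights, q = 0.9)` is the share of the total
(area-weighted) flux carried by the leaves above the q-th area-weighted
quantile, with the boundary leaf counted fractionally so the top group holds
exactly `1 - q` of the leaf area. With equal leaf areas this is the top 10%
of leaves by count. For an exponential population the top-decile share has
the closed form `0.1 (1 + ln 10) ~ 0.33`, a useful anchor: values well above
it indicate a distribution more concentrated than exponential. Histograms
default to Freedman-Diaconis binning; daily totals integrate per-leaf
trajectories trapezoidally over daylight (solar zenith < 90 deg) only.
Voxel binning assigns planar primitives by centroid, with boundary ties to
the lower-index cell.

## The diurnal case study

`run_diurnal()` orchestrates the full experiment:

1. build the canopy (dense scenario: 3 x 3 trees at 1 tree per 36 m^2 with
   periodic lateral boundaries, statistics taken from the central tree;
   isolated scenario: one tree with open surroundings and a 6 m ground
   margin);
2. generate clear-sky weather (below) and simulate every daylight 15-min
   step: one collimated trace per step, diffuse/scattered shortwave through
   the cached exchange operator, then a damped (factor 0.5) fixed-point
   sweep alternating longwave exchange, stomatal conductance, and the
   secant energy balance until the largest per-leaf temperature change is
   under 0.05 K (warm-started from the previous step), and finally the
   coupled A-C_i solution;
3. integrate per-leaf absorbed PAR, transpiration and net assimilation over
   daylight; delete every leaf whose daily net CO2 assimilation is negative
   (daily respiration exceeding assimilation); rerun the pruned canopy with
   identical settings; and report per-step population statistics, daily
   integrals, top-decile shares and ten seeded leaf trajectories.

Wood is an occluder and a longwave source pinned at air temperature, but
not an energy-balance surface — bark stays near air temperature at this
scale and its physiology is not of interest. Ground tiles are opaque,
non-transpiring one-sided surfaces solved like leaves (PAR albedo 0.15, NIR
0.30, emissivity 0.95). Rays leaving an open (non-periodic) scene downward
see the mean modeled ground exitance rather than a void. Air temperature
and humidity are horizontally and vertically uniform by construction.

**Synthetic weather.** The measured forcing the original experiment used is
not published numerically, so `synth_weather()` stands in: a sinusoidal air
temperature (minimum 16 C at 05:00, maximum 36 C at 15:00 — a typical
Central Valley midsummer day), humidity anti-phased between 0.20 and 0.75,
and clear-sky radiation computed per step. Direct and diffuse shortwave come
from a broadband clear-sky transmittance product (Rayleigh, ozone, mixed
gas, water vapor, aerosol terms with published broadband coefficients, each
overridable; aerosol optical depth 0.12, a typical agricultural-valley
summer haze), split equally into PAR and NIR; downwelling longwave uses a
clear-sky effective emissivity increasing with precipitable water, which in
turn is estimated from an exponential-in-dewpoint relation. The simulated
date is 2022-06-21 at 36.6 N, 119.5 W (UTC-8). These are the study
conditions; they are configurable but are not tuned per run.

**Problem sizes.** The shipped configuration uses 200 direct and 500
diffuse rays per primitive, ~167,000 leaves before pruning in the dense
scenario, and 15-min steps — chosen so a full two-scenario reproduction
(including precursor runs) completes on a single desktop core. The
acceptance tests for the radiation solver use 1e4 rays per receiver, where
the slab transmission error is within 2% of the closed form.

## What the synthetic conditions do and do not show

The generator reproduces the statistical structure that drives the
population results — explicit crowns with realistic density, constant leaf
size, spherical leaf angles, clear-sky forcing — but not any particular
orchard: the branching parameters are plausible rather than measured, the
real leaf-angle distribution of the field canopy was only available
graphically and is replaced by the spherical one, and the weather is an
idealized clear day rather than station records. Passing tests therefore
demonstrate that the coupled machinery reproduces the *population-level*
behavior (nearly exponential absorbed-light distributions, most leaves
below air temperature at midday, top-decile shares and their
canopy-vs-isolated ordering) under stated conditions — not that any single
leaf trajectory matches a measured leaf.

## Numerical choices collected

* Secant tolerance 1e-4 W m-2, bracket `T_a +/- 20 K`, max 100 iterations.
* Coupling sweep: damping 0.5 on the temperature update, tolerance 0.05 K,
  cap 30 sweeps (cold starts need ~12; warm-started steps converge in 1-3).
* A-C_i: analytic per-branch quadratic initialization, damped polish to
  0.01 umol mol-1 (1e-7 inside fitting).
* Scattering: 3 passes, residual reported.
* Ray counts: 200 collimated / 500 hemisphere per primitive by default.
* Tie-breaks: voxel binning to the lower-index cell; top-decile boundary
  leaf included fractionally.
* Degenerate inputs are errors with specific messages: collinear triangles,
  all-masked patches, non-normalized inclination tables, all-zero flux
  populations, out-of-span weather queries, non-converged solves (with the
  worst leaf identified).
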