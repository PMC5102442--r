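---
title: "Peridynamic modelling of lipid membrane rupture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peridynamic modelling of lipid membrane rupture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimem)
```

## The physical problem

When a double lipid bilayer membrane spreads on a high-energy substrate, the
upper (distal) bilayer eventually ruptures spontaneously.  Experimentally the
ruptures take two morphologies: smooth, petal-edged *floral* pores, and
branched, channel-like *fractal* patterns.  Interconnections between the two
bilayers — pinning sites, presumably bridged by Ca²⁺ ions — are suspected to
nucleate the ruptures, and to stiffen the distal sheet in shear, which in
turn selects the morphology.

`perimem` simulates this process with state-based peridynamics: the membrane
is a two-dimensional sheet of material points, each bonded to every
neighbour within a finite horizon δ.  The equation of motion is an integral
(here: a sum over bonds), so displacement discontinuities — cracks, pores —
require no special treatment: a bond stretched beyond a critical value
breaks irreversibly, loads redistribute, and rupture patterns emerge on
their own.

## Discretisation

The membrane is a disc of diameter $D_0$ sampled on a square lattice of
spacing $h$, with per-particle area $A = h^2$ and thickness $\epsilon$.
Defaults are the study conditions throughout: $D_0 = 200\,\mu m$,
$h = 1\,\mu m$, $\epsilon = 5\,\mathrm{nm}$, horizon $\delta = 3\,\mu m$.
The neighbourhood is the *closed* ball $0 < \|\xi\| \le \delta$, so lattice
points at exactly the horizon are bonded; this makes bond counts exact
integers (an interior particle has 28 bonds at $\delta = 3h$) and the
weighted volume an exact lattice sum ($m = 136\,h^4$).  A square lattice
rather than a hexagonal one keeps $A = h^2$ exact and matches the
spacing-only description of the discretisation.

Pinning sites are single fixed particles.  By default they are drawn
uniformly over the interior disc (radius $D_0/2$ minus the loading-layer
width), with draws that land in the driven layer resampled, so a pinned
particle is never simultaneously driven; an explicit coordinate list
(nearest lattice point, ties to the lowest index) lets specific layouts be
replayed.

## Constitutive model

The linear peridynamic solid (LPS) decomposes the bond force into a
dilatational and a deviatoric part.  With constant influence function
$\omega \equiv 1$ (the simplest choice consistent with the framework, and
the one that keeps the lattice oracles exact), the weighted volume and
dilatation are

$$m_i = \sum_j \|\xi_{ij}\|^2 A, \qquad
\theta_i = \frac{2}{m_i} \sum_j \|\xi_{ij}\|\, e_{ij}\, A,$$

with bond extension $e = \|y_j - y_i\| - \|\xi\|$ over intact bonds.  Both
depend only on deformed lengths, hence are exactly frame-indifferent, and
$\theta = \mathrm{tr}\,\varepsilon$ for uniform small strain.  The scalar
force state is

$$t_{ij} = \frac{2K}{\epsilon\, m_i}\,\theta_i\,\|\xi\|
        + \frac{8G}{\epsilon\, m_i}\left(e - \tfrac{1}{2}\theta_i\|\xi\|\right),$$

directed along the deformed bond, assembled pairwise
($f_i \mathrel{+}= \epsilon\,(t_{ij}+t_{ji})\,M_{ij}A$, with the opposite
sign on $j$) so that total momentum balances to machine precision.

Two design points deserve emphasis:

* **The $1/\epsilon$ factor** mirrors the 3D-to-2D reduction of the LPS
  weighted volume ($m_{3D} = \epsilon\, m_{2D}$) and cancels the thickness
  factor in the equation of motion.  Omitting it leaves the stress of a
  statically strained patch unchanged but makes the dynamics hundreds of
  times too compliant — the elastic wave speed drops below the loading
  speed and the simulation behaves qualitatively wrongly.
* **$K$ and $G$ are the areal (2D) moduli.** A literal plane-stress
  reduction of a 3D material with these moduli has areal bulk stiffness
  $9KG/(3K+4G)$, which vanishes for a fluid film ($G = 0$) — a zero-shear
  membrane would then carry no stress and could never rupture, contradicting
  the central zero-shear floral-rupture scenario.  Treating the moduli as
  areal gives $\sigma = K\,\mathrm{tr}\,\varepsilon\, I +
  2G\,\mathrm{dev}\,\varepsilon$, which keeps a fluid film stiff in
  dilatation.  The coefficients $2K/(\epsilon m)$ and $8G/(\epsilon m)$
  follow from angular averages over an isotropic neighbourhood; on the
  $\delta = 3h$ lattice the residual anisotropy of the deviatoric term is
  about 3.5 %, and the uniform-strain patch test (`stress_through_cut()`
  against `elastic_stress_2d()`) holds within 2 % for
  $G \in \{0, 2.5, 5, 10\}$ MPa — the 5 % acceptance margin is comfortable.
  The reported Poisson ratio (`poisson_ratio()`, 0.5 at $G=0$ down to 0.125
  at $G = K = 10$ MPa) uses the 3D isotropic relation, matching the printed
  0.13–0.5 range of the shear sweep.

Bond breaking uses a critical stretch $s_c = 0.15$: a bond whose stretch
$(\|y_j-y_i\| - \|\xi\|)/\|\xi\|$ exceeds $s_c$ is removed, both directions
at once, irreversibly; compressed bonds never break.  Breaking is evaluated
once per *accepted* time step — not inside the fixed-point iteration — so
the implicit solve stays well-posed.  Per-particle damage is the broken
fraction of the particle's initial bonds; the weighted volume stays frozen
at the initial bond set, with damage entering through the force sums, the
standard treatment in the LPS framework.

Short-range repulsion prevents interpenetration:
$f = \min\{0, C_{sr}(\|y_j-y_i\| - d_{pi})\}\,\hat u_{ij}$ with
$d_{pi} = \min\{0.9\|x_j - x_i\|, 1.35h\}$, applied between *all* pairs in
range, bonded or not, over the current configuration.  The printed grouping
of the prefactor is typographically ambiguous; we implement
$C_{sr} = c\,K\pi/\delta^5$ with $c = 2.7\times 10^{-8}$ and make $C_{sr}$
directly overridable.  Under any plausible grouping of the printed
constants the resulting force is orders of magnitude below the bond forces
at comparable deformation, i.e. a weak anti-overlap regularisation; the
deadband (zero force at separations $\ge 1.35h$) is exact.  Exactly
coincident particles repel along $+x$, deterministically.

## Time integration

Rupture unfolds over tens of milliseconds of simulated time, far too long
for explicit integration at the elastic time scale, so the equation of
motion is advanced with the implicit trapezoidal rule solved by fixed-point
iteration (at most 8 iterations, tolerance $10^{-6}$), with two standard
accelerations:

* **Mass scaling**: the density $\rho = 1000\,\mathrm{kg/m^3}$ is scaled by
  $10^8$, enlarging the stable step by $10^4$.  The acceptance suite checks
  that rupture morphology is statistically indistinguishable across
  $10^4$–$10^8$.
* **Adaptive stepping**: a step whose iteration fails to converge — or
  whose iterate change *grows*, the signature of a divergent stiff mode —
  is rejected and retried at half the step; convergence within 3 iterations
  grows the step by 1.2×, capped at `dt_max`.  The controller constants are
  configurable; these defaults are our own realisation of the adaptive
  framework, whose exact constants are not published.

The fixed-point iterate starts from a forward-Euler predictor.  Kinematic
constraints — pinned particles at their reference positions, boundary-layer
particles at the prescribed radial velocity — are re-imposed by projection
after every iterate, so they hold exactly at every accepted step.
Convergence is measured as the largest position change between successive
iterates *relative to the lattice spacing*; an absolute measure tightens
automatically where crack-tip dynamics localise.  With these choices the
controller settles near $10^{-4}\,$s for the quiescent full-density-scaled
membrane, matching the reported typical step, and second-order accuracy is
verified against the closed-form harmonic oscillator.

### Loading and startup

The membrane edge advances by tank-tread motion in the physical system;
numerically, every particle within 10 μm of the rim is driven radially
outward at 200 μm/s.  Driving a layer rather than the rim row mitigates
spurious edge fracture from the bond deficit at the free boundary.  Two
consequences of this loading deserve documentation:

* **Startup**: launching the layer impulsively from rest deposits a
  lattice-scale displacement jump at the layer junction which the
  zero-shear membrane (whose force is dilatation-mediated) cannot relax;
  bonds there would tear unphysically within a millisecond.
  `run_simulation()` therefore starts from the quasi-static co-moving
  velocity field (uniform radial strain rate in the interior, the
  prescribed velocity in the layer), which is the transient-free initial
  condition for constant-rate expansion.
* **Rim ring rupture**: the driven layer translates radially without
  stretching radially, so its tension is roughly half the interior's, and
  the junction bonds inevitably tear as a circular ring as expansion
  proceeds.  The original study encountered the same artefact — its binary
  rupture images note that the circular rim around the expanding membrane
  was removed manually.  `perimem` automates the removal: the mask drops
  the hull-touching contour component, onset statistics
  (`rupture_onset()`, `count_nucleation_sites()`) exclude particles within
  $2\delta$ of the layer junction, and `detect_pores(region_radius = )`
  filters pores by centroid.  At late expansion the detached edge can peel
  inward as a dynamic fracture cascade even without pins; the pin-free
  control is therefore meaningful up to $D/D_0 \approx 1.05$, while pinned
  membranes nucleate interior pores by $D/D_0 \approx 1.035$ — the
  pins-versus-control contrast the nucleation checks rely on.

The run's progress coordinate is the expansion ratio $D/D_0$ (twice the
maximal radial coordinate over the initial diameter), and runs stop at a
target ratio rather than a wall time.  The default stop, $D/D_0 = 1.5$, is
where bond breaking has plateaued on the scaled fixture — the pattern is
developed, mirroring measuring the printed late-stage snapshots.  Snapshots
are cadenced in simulated time so the adaptive step cannot alias the
output.

## Morphology analysis

`rasterize_rupture()` draws discs (radius $0.75h$, the smallest that tiles
the square lattice without gaps) around every particle with damage below
0.5, takes the void as the complement within the convex hull of all
particles, and emits the void's contour pixels at 0.5 μm/px (two pixels per
particle spacing).  `detect_pores()` labels the void 8-connected,
excluding components that touch the exterior.  `box_count_dimension()`
covers the mask with grids of boxes — powers of two from 2 px to a quarter
of the image side, anchored at the image origin (the plain grid method; no
offset averaging) — and reads the fractal dimension $D$ off the slope of
$\log N$ versus $\log s$ by least squares.  The estimator is validated
against analytic sets: a line ($D = 1$), a filled square ($D = 2$) and a
level-7 Sierpinski triangle ($D = \log 3/\log 2 \approx 1.585$), each
recovered within ±0.05 and stable under halving the raster resolution.
Fits with $R^2 < 0.95$ carry a warning; empty masks are refused.

`morphology_report()` tabulates pore count, void area and $D$ per
snapshot.  The final-snapshot $D$ is the headline statistic; the
"floral-like"/"fractal-like" label attached at a threshold of $D = 1.4$ is
a convenience only and no quantitative check depends on it.

## The synthetic-data generator and what passing tests mean

All inputs are generated by the package itself.  The generator produces
three kinds of object: uniformly strained lattice patches (the elasticity
calibration), analytic fractal rasters (the box-counting validation), and
scaled membranes — full study conditions except the diameter.  The scaled
fixture is 60 μm (~2,800 particles; seconds per run), chosen so that
several pores fit at $h = 1\,\mu m$; mass-scaling sweeps use 40 μm because
the $10^4$ arm is ~100× more steps.  The default test suite runs the
nucleation fixture at $G = 0$ with 4 scattered pins over 5 seeds, the
morphology sweep at $G \in \{0, 2.5, 7.5\}$ MPa with 6 pins fixed per seed
over 5 seeds, and the mass-scaling sweep at $G = 5$ MPa over 3 seeds ×
$\{10^4, 10^6, 10^8\}$; `scripts/acceptance.R` recomputes the same
statistics from seeds derived from its `--seed` argument.  Full-scale
200 μm runs (31,417 particles, hours each) reproduce the published fractal
dimensions' regime and are provided as an extended-suite runner
(`inst/extended/full_scale_fractal.R`) rather than as part of the default
suite.

What the scaled fixtures demonstrate: nucleation at pins, the
floral-to-fractal trend of $D$ with shear modulus, insensitivity to mass
scaling, and every conservation/irreversibility invariant.  What they do
not demonstrate: the absolute fractal dimensions of the full-scale
patterns ($D$ grows with pattern extent; scaled fixtures saturate around
1.0–1.3, below the published 1.56–1.66), rate effects beyond the single
200 μm/s loading rate, and any feature of real membranes outside the model
— substrate hydrodynamics, inter-leaflet friction and Ca²⁺ binding
chemistry are all outside scope, and genuinely molecular scales admit no
true fractality at all.

## Numerical edge cases

* Bonds whose deformed length vanishes have no defined LPS direction; their
  contribution is skipped for the step (counted internally) and the contact
  machinery handles the overlap.
* Isolated particles (no initial bonds) have zero weighted volume, are
  excluded from force evaluation, and report damage 1.
* Step rejection never mutates state; `dt` underflow aborts the run with
  the last state preserved, as does any non-finite position.
* All kernels are single-threaded with fixed summation order: identical
  configurations reproduce bit-identical trajectories.

## Parameters at a glance

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `diameter` | 200 | μm | initial membrane diameter $D_0$ |
| `spacing` | 1 | μm | lattice spacing $h$; $A = h^2$ |
| `horizon` | 3 | μm | bond neighbourhood radius δ |
| `thickness` | 0.005 | μm | membrane thickness ε |
| `layer_width` | 10 | μm | driven boundary layer |
| `K` | 10 | MPa | areal bulk modulus |
| `G` | 0–10 | MPa | areal shear modulus (0 = fluid) |
| `rho` | 1000 | kg/m³ | physical density |
| `mass_scale` | 1e8 | — | density scaling for the time step |
| `critical_stretch` | 0.15 | — | bond-breaking stretch $s_c$ |
| `contact_scale_c` | 2.7e-8 | — | short-range force scale $c$ |
| `loading_rate` | 200 | μm/s | radial rim speed |
| `max_fp_iterations` | 8 | — | fixed-point cap per step |
| `fp_tolerance` | 1e-6 | — | iterate change / lattice spacing |
| `stop_ratio` | 1.5 | — | target $D/D_0$ |

## A worked example

```{r example, eval = FALSE}
cfg <- make_scaled_membrane(60, n_pins = 6, seed = 1,
                            material = material_model(K = 10, G = 7.5))
traj <- run_simulation(cfg)
rupture_onset(traj)$distances_to_pin   # nucleation sits at the pins
morphology_report(traj, snapshots = length(traj$snapshots))
plot(traj)                              # damage field with pins marked
```
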