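---
title: "Coarse-grained actin filament mechanics and superhelix analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained actin filament mechanics and superhelix analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Mechanical force reshapes filamentous actin (F-actin). Under myosin-scale
loads, filaments can adopt superhelical ("spiraling") architectures whose
geometry — wavelength, transverse amplitudes, elliptical cross-section,
lattice twist and rise — carries mechanical information. This package
provides a coarse-grained simulator of an actin filament as a bead-spring
network, the calibration procedures that pin its stiffness constants to
published mechanical observables, and the geometric analytics that detect
and quantify superhelical character in simulated filaments, 3D traced
filaments, 2D segmentation maps and fitted protomer models.

This vignette records the model, its assumptions, the tunable parameters,
the design decisions taken where the methodology was genuinely open, and
what the synthetic-data tests do and do not establish.

## The filament model

Each actin subunit is a spherical particle at its centroid. The canonical
filament is two right-handed long-pitch strands wrapping around each other,
equivalent to a left-handed single-start (genetic) helix with rise
27.8 Å and twist −166.67° per subunit. `build_canonical_lattice()` places
subunit $i$ at cylindrical coordinates $(r,\; i\,\Delta\phi,\; i\,\Delta z)$.

The subunit-centroid radius $r$ is not fixed by the rise/twist alone; the
package default is 25 Å, an approximation to the protomer-centroid radius
of the canonical structure, exposed as `lattice_params(radius = )`. All
positions are stored in nm internally; Å and degrees are used at the user
boundary.

`derive_topology()` connects the network:

* bonds: genetic-helix contacts $(i, i+1)$ ("lateral", crossing between
  strands) and long-pitch strand contacts $(i, i+2)$ ("axial");
* angles: all $\binom{4}{2} = 6$ triplets centred on each interior
  particle whose arms are two of its four bonded neighbours
  $\{i-2, i-1, i+1, i+2\}$;
* dihedrals: one quadruplet per particle along each helical path,
  $(i, i+1, i+2, i+3)$ along the genetic helix and $(i, i+2, i+4, i+6)$
  along the long-pitch strand, with multiplicity $n = 1$.

This is the unique enumeration consistent with six angles and two
dihedrals per particle given the bond pattern. The energy is

$$V = \tfrac{1}{2} k_l (l - l_0)^2
    + \tfrac{1}{2} k_\theta (\theta - \theta_0)^2
    + k_\phi \left[ 1 - \cos(n\phi - \phi_0) \right],$$

with every rest value measured on the generating configuration, which is
therefore the exact zero-energy state (asserted to $10^{-18}$ pN nm in the
tests). One $k_l$ is shared by lateral and axial bonds by default
(`mechanical_params(k_l_axial = )` overrides). Protomer deformations and
nucleotide-state transitions are outside the model.

## Dynamics

`run_dynamics()` integrates Langevin dynamics with a BAOAB splitting;
setting `thermostat_on = FALSE` gives velocity-Verlet vacuum dynamics.
Forces are analytic gradients (Blondel–Karplus form for dihedrals),
verified against central finite differences to $10^{-4}$ pN.

Numerical choices:

* **Mass** is a nominal 1 pN ns² nm⁻¹ per particle; only configurational
  statistics matter for the questions asked of the model.
* **Friction** defaults to Stokes' law for a 2.5 nm sphere in water at
  298 K (≈ 42 pN ns nm⁻¹), `stokes_friction()`.
* **Time step** defaults to 1/20 of the fastest harmonic period implied by
  $(k_l, m)$. The stiffest dihedral modes exceed this frequency; with the
  thermostat on, BAOAB keeps them stable and slightly under-resolved,
  which affects the stiff-mode amplitudes but not the soft bending and
  twisting modes the analyses measure. Energy-conservation checks
  (thermostat off) use a smaller step (2 × 10⁻⁴ ns), where total energy is
  conserved to < 0.1% over 10⁴ steps. A divergence guard aborts any run
  whose coordinates leave a sanity bound, naming the step.
* Integration is bit-reproducible for a given seed (R's RNG drives the
  thermostat).

Force protocols mimic myosin loading: the first five subunits are fixed
and each of the last five receives 5 pN along the initial filament axis
(25 pN total), directed away from the fixed end for tension and toward it
for compression. The direction is held fixed along the initial axis during
the run; a current-axis mode would be a trivial extension but is not
needed for the packaged analyses. In `apply_release` mode the external
force is removed after the apply phase; if no apply duration is given, the
run continues until the axial extension plateaus (0.05 nm change per
10-frame chunk), then releases for an equal duration.

Compression runs keep the thermostat on: a perfectly straight, noiseless
column cannot break symmetry, so thermal fluctuations are the physical
nucleation seed for buckling.

## Calibration

Two procedures calibrate the stiffness constants.

**Stretch stiffness.** A 39-subunit filament is relaxed deterministically
(L-BFGS on the elastic energy minus the external work, residual force
< 10⁻³ pN) under a series of axial tensions; the least-squares slope of
force against equilibrium axial extension is the stretch stiffness.
`scan_stiffness()` evaluates a $(k_l, k_\theta)$ grid and selects the
point closest to a target: 37 pN/nm reproduces the published ATP-state
stiffness and selects $(k_l, k_\theta) = (390, 150)$; 31 pN/nm (ADP
state) selects $(270, 300)$. These grid selections are packaged as
`calibrated_params()`. The measurement is deterministic; extension is the
projected distance between the end-group centroids.

**Twist variance.** Thermal fluctuations of a 100-subunit filament are
simulated and the per-subunit variance of the twist deviation (zero-mean
maximum-likelihood fit, i.e. the mean of squared deviations) is
accumulated along subunit index, excluding 20 subunits at each end.
`scan_twist_stiffness()` selects the $(k_\phi, k_\theta)$ pair whose
cumulative-variance curve is closest to a reference curve in least
squares. The quantitative experimental reference curve is not available
as text, so the packaged reference is simulator-generated, and a real
curve can be supplied as a numeric vector (e.g. read from CSV). All grid
points share the reference's integrator seed (common random numbers), so
self-consistency recovery of generating parameters is exact at grid
resolution. With independent noise realisations, the cumulative-variance
curve at desk-scale durations (hundreds of ns) is dominated by the
seed-dependent transient of the slow azimuthal modes, and neither
$k_\phi$ nor $k_\theta$ (whose influence is the weak twist-bend coupling)
is identifiable; resolving them against an external reference requires
microsecond-scale sampling. The common-random-numbers design is therefore
not an optimisation but the condition that makes desk-scale calibration
well-posed.

Because no external target pins $k_\phi$, its default (2000 pN nm) is set
from the scale of F-actin's measured torsional rigidity
(≈ 8 × 10⁻²⁶ N m², about 1° of thermal twist per interface). The
cantilever bending rigidity that emerges from the calibrated sets
corresponds to persistence lengths of 11–16 μm, inside the experimental
range for actin, which was not imposed — a useful consistency check.

A caveat worth recording: the midpoint-projection twist algorithm measures
smooth (wavelike) twist modulations essentially exactly (< 0.05°), but
attenuates spatially white per-interface twist noise by roughly half,
because the locally derived axis segments are perturbed by the same noise.
The Frenet/transported-frame measurement (`instantaneous_twist()`) does
not share this coupling (white-noise recovery correlation 0.99). Both are
provided; the calibration pipeline uses the midpoint method, and since
reference and scan are measured identically, the calibration comparison is
unaffected.

## Helical parameter measurement

For deformed filaments, `fit_axis_spline()` builds the central axis from
the midpoint construction, smooths it with a 5-subunit moving average —
enough to remove the ~2.2-subunit micro-helix the construction leaves
(residual < 0.01 nm) while passing superhelical wavelengths ≥ 100 nm
essentially unchanged — and reparameterises by arc length. The radius is
fit separately with a univariate smoothing spline, so it varies freely
along the filament. When the axis points are straight to within the
micro-helix residual (0.2 nm), the axis is taken as the exact best-fit
line, with its direction refined from the chain's mean screw rotation;
this makes the canonical round trip exact to 10⁻⁹ relative.

Rise is the arc length along the axis between the orthogonal foot points
of consecutive protomers; twist is the rotation of the protomer azimuth in
a normal–binormal frame transported along the axis, seeded from the
Frenet frame where curvature is defined and falling back to parallel
transport on straight stretches (recorded in the output's `frame`
attribute). The exact rotation convention "along the normal–binormal
plane" admits more than one reading; the transported-
azimuth implementation is our documented interpretation, validated by
round trips on modulated lattices (sinusoidal rise programs recovered to
0.3 Å; twist programs to 0.2° in the mean). Note that for filaments whose
axis is genuinely curved and torsional, per-interface rise oscillates with
subunit azimuth — a projection effect of the tilted local tangent, not a
lattice deformation — which is part of what the wavelike experimental
profiles contain. Three-copy stitching (`measure_helical_profile(stitch
= 3)`) extends the chain by its own mean screw transform and reports only
the central copy, suppressing edge artifacts.

## Trace analysis

Manual 3D filament traces are smoothed with per-coordinate splines under a
fixed smoothing factor (150, in squared-Å of residual, the scale of
manual-picking jitter) and resampled at 9.6 Å. Curvature and torsion come
from finite differences of the resampled curve (closed-form circle and
helix values reproduced to 1%).

Oscillatory segments of 350–500 nm are selected where curvature exceeds
1.5 μm⁻¹ and its component along the trace's transverse principal
direction changes sign at least twice — our operationalisation of "high,
oscillating curvature and torsion", which in practice is a visual
judgement during tracing. Each segment is PCA-decomposed and aligned: centred on
the near-maximal |PC2| peak closest to the segment midpoint, PC2 negative
at the centre (second derivative positive), inverted decompositions
resolved by a deterministic choice between the two proper-rotation
variants. This makes alignment exactly invariant to traversal order and
rigid motion (asserted to 10⁻⁸ in the tests). Filament polarity is not
assigned.

Within a common 350 nm window, the wavelength is the first autocorrelation
peak (after a σ = 2 nm Gaussian blur) of the PC2 signal regridded evenly
along PC1 — along the filament axis, not along arc length, which would
inflate wavelengths by the path-stretch factor. Unbiased ACF normalisation
and parabolic peak refinement remove the finite-window bias. The
fractional phase offset is the cross-correlation lag between PC2 and PC3
divided by the wavelength, folded into [0, 0.5]; an ideal circular
superhelix gives 0.25 (quarter wavelength). Amplitudes are maximum
absolute excursions along PC2/PC3 (the major/minor cross-section axes);
segments below 15 nm are flagged insignificant. Finite non-integer-period
windows inflate the PC-amplitude of a pure sinusoid by up to ~10% through
the window mean — inherent to PCA amplitudes on finite windows and left
uncorrected, since experimental amplitudes carry the same convention.
Whether experimental ellipse axes should instead be measured by ellipse
fitting is unresolved; PC amplitudes are the package default.

The segment-versus-ice-plane angle fits the plane by PCA of marker points,
projects the plane normal orthogonally to the segment's PC1 and measures
the angle of PC2 against the plane (0° in-plane, 90° along the normal).
`ks_uniformity_test()` compares an angle sample against a fitted or
standard normal reference (both modes provided; either convention is
defensible).

## Force-response phenomenology

`force_response_suite()` packages the study conditions used to probe the
force response at desk scale: 100-subunit filaments (a scaled-down version
of the 400-subunit production geometry), the ADP-state calibrated
parameters, water friction at 298 K, constant runs of 2.5 × 10⁵ steps and
apply/release runs of 10⁵ + 4 × 10⁵ steps, five seeds. Which
nucleotide-state stiffness drove the original force runs is not stated in
the source; the ADP set is our choice, made because its slightly stiffer
bending keeps the tension-held filament's thermal amplitude clearly below
the 15 nm significance cutoff at this filament length — the length itself
was chosen for the same reason (taut-string fluctuations grow as √L and
would straddle the cutoff at 150+ subunits).

Under these conditions: constant compression buckles essentially
immediately into spirals of 30–45 nm amplitude; constant tension stays
near its ~13 nm thermal baseline (the amplitude statistic is an extreme
value over frames, so single seeds can spike — the packaged assertions use
seed medians and majorities); transient tension spirals during the release
phase as the filament recoils; transient-compression spirals persist into
the release phase; and the spiral wavelength at formation (the first frame
crossing 15 nm) is shorter for compression-driven buckling, which forms
under load, than for recoil-driven spiraling, which forms near zero force
— the ordering is asserted on seed medians. All spiral-forming runs show
elliptical cross-sections (PC2 > PC3 amplitude). The transverse amplitude
itself is measured as the maximum |PC2| excursion of the central-axis
points, mirroring the significance cutoff's use.

These runs are far shorter than full thermal equilibration of the longest
bending modes; the phenomenology is a statement about the response on
myosin-stroke-like timescales under the stated conditions, not about
equilibrium ensembles.

## Curvature model

Free filament curvature follows a Boltzmann distribution set by the
bending energy $E = \tfrac{1}{2} k_B T\, L_p L \kappa^2$, giving
$P(\kappa) \propto \exp(-\alpha L_p L \kappa^2 / 2)$ with a multiplicative
adjustment $\alpha$ standing in for a differing persistence length. The
printed form of the probability omits a visible minus sign; the decaying
(negative-exponent) form is implemented, as required by the energy and by
normalisability. The grid normalisation (default 0–20 μm⁻¹, step 0.05)
mirrors the discrete sum; `curvature_density()` is the continuous
half-Gaussian cross-check. The maximum-likelihood $\alpha$ has the closed
form $1 / (L_p L \,\overline{\kappa^2})$, which the tests verify against a
numeric optimiser and recover from synthetic samples to 2%.

## Segmentation picker

2D probability maps are binarised at 0.3, skeletonised (Zhang–Suen),
dilated by 8 px to link broken filament ends, re-skeletonised, pruned of
branches shorter than 8 px, and cleared within 16 px of junctions —
junctions being pixels whose 8-neighbourhood crossing number is ≥ 3, not
merely pixels with three neighbours, which would fragment every diagonal
staircase. Remaining fragments are joined across cleared junctions when
their endpoint tangents are antiparallel (the pair minimising tangent
discontinuity wins when several meet). Each track gets a smoothing spline
(half a squared pixel of residual per path point) resampled at 1 px;
signed curvature (positive = left turn along traversal, traversal fixed
from the lower-index endpoint) is sampled every 3 px with the terminal
50 px omitted.

A filament is superhelical if it contains a run of ≥ 200 Å with
κ ≥ +1.5 μm⁻¹ and another with κ ≤ −1.5 μm⁻¹ — straight filaments and
uniplanar arcs fail. Picks are sampled every 100 Å (the pre-suppression
spacing is not fixed by the picking conventions; it is exposed as a
parameter) and per-filament greedy non-maximum suppression retains picks
no closer than 830 Å, scanning in along-filament order. The retained set
equals the exhaustive greedy optimum (verified for ≤ 12 picks). Output is
a minimal RELION-style STAR file plus a data-frame mirror.

## Subdomain displacements

`superpose()` is a Kabsch least-squares superposition restricted to proper
rotations (reflections rejected via the determinant correction), over all
shared Cα by default with an optional fit subset. `subdomain_vectors()`
averages per-residue displacement vectors within the seven printed residue
ranges (7-35, 35-72, 72-147, 340-377, 147-183, 272-340, 183-272); the
overlapping boundary residues are kept as printed, so a boundary residue
contributes to two means. The 15× scaling seen in display figures is a
visualisation convention and is never applied to data. Per-protomer output
is the default; pooling across protomers is the caller's one-liner.

## Synthetic data: what passing tests show

Every analysis stage is tested as a generator → analyzer round trip with
machine-readable ground truth: ideal and noisy superhelix traces (marker
noise default 1 nm, the scale of manual tracing jitter), planar arcs,
straight traces, lattices with programmed rise/twist modulations and
superhelical axis paths, rasterised segmentation maps with Gaussian
cross-sections (so the 0.3 threshold is meaningful), half-Gaussian
curvature samples, white-twist-noise trajectories, and protomers with
rigidly shifted subdomains. All generators are pure functions of their
parameters and a mandatory seed.

What these fixtures do **not** emulate: missing-wedge and denoising
artifacts of tomograms, structured segmentation noise (carbon edges, ice
contamination), correlated tracing errors, protomer-fold detail, or
crowded fields of overlapping filaments. Passing the synthetic benchmarks
therefore establishes the correctness of the geometry and statistics, not
the robustness of the full experimental pipeline to those artifacts.

## Problem sizes

The packaged test and reference computations use 100-subunit lattices for
geometry, 39 subunits for force-extension (the size used by the published
force-extension simulations), 100 subunits for thermal twist statistics at
2 × 10⁴ steps, and the five-seed force-response suite described above —
sizes chosen so the full suite is a desk-scale computation while every
qualitative result it asserts also holds at larger sizes we explored
during development (up to 400 subunits and 2 × 10⁶ steps).

## Known limitations

* The calibration targets constrain $(k_l, k_\theta)$ only along a
  degenerate contour; the packaged $k_\theta$ split is fixed by the scan
  grids, and $k_\phi$ by a literature-scale torsional rigidity, not by a
  packaged experimental curve.
* The integrator's default step under-resolves the stiffest dihedral
  modes (thermostatted runs only; see above).
* PCA amplitudes on finite windows carry a ~10% upward bias for pure
  sinusoids; wavelengths are unbiased.
* The midpoint-projection twist attenuates spatially white twist noise by
  about half (smooth modulations are exact).
* Excluded-volume, self-contact and hydrodynamic coupling are absent, so
  post-buckling amplitudes at long times are not physical.
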