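---
title: "Methods: simulating and analysing guest diffusion in single MOF crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing guest diffusion in single MOF crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experiment this package models

A colourless mesoporous crystal (the motivating system is Tb-mesoMOF, a
terbium/TATB framework with 3.9 and 4.7 nm cages connected by 1.3 and
1.7 nm windows) is immersed in a solution of an intensely red guest --
vitamin B12 (cobalamin), a rigid molecule of roughly
1.41 × 1.83 × 1.14 nm. Because the guest is coloured and the host is not,
an ordinary bright-field microscope can watch the guest diffuse in
(the crystal reddens, corners first, then edges, then faces, then the
interior) and back out (the colour fades and plateaus). The quantitative
observable is a *mean differential red-intensity trace*: each frame is
subtracted from the first (reference) frame, the red channel of the
difference is kept, and its mean over the frame is plotted against time.
From the release trace one extracts a characteristic half-intensity time
$t_D$ and a spot-change length $\omega$, and estimates a diffusion
coefficient with the FRAP-style formula

$$D = \frac{\omega^2}{4\,t_D},$$

while Brownian-ensemble ground truth uses the mean-square-displacement
relation $\langle x^2\rangle = q_i D t$ with $q_i = 2, 4, 6$ for 1-, 2-,
3-dimensional diffusion.

Raw video of such experiments is rarely published. The package therefore
ships a synthetic-data generator -- a 3-D diffusion solver plus an optical
renderer -- whose output feeds the *same* image pipeline a microscope
recording would. Every stage of the analysis is validated against that
generator or against closed-form oracles.

# The simulator

## Diffusion model

The crystal is an axis-aligned box of physical size `extents` (µm),
half-open `[0, extent)` per axis, discretised into isotropic cubic voxels
(`voxel_pitch` µm; voxel `i` spans `[(i-1)h, ih)`, 1-based indices as
everywhere in R). The state is a fractional guest occupancy field
$u \in [0,1]$ per voxel; occupancy 1 corresponds to the saturation load
(0.33 mg guest per mg MOF for the motivating system).

The solver is a forward-time centred-space (FTCS) scheme in conservative
(flux) form with spatially varying diffusivity, compiled in C++ for
speed. Faces in contact with solution are Dirichlet boundaries: their
outermost voxel layer is held at the bath occupancy (1 for uptake from a
saturated bath, 0 for release into pure solvent). Sealed faces are
zero-flux, so a fully sealed crystal conserves total occupancy to
floating-point rounding -- the test suite asserts 1e-9 relative over 1000
steps. The stability bound $\Delta t \le h^2 / (6\,\max D)$ is *enforced*:
the solver refuses a larger step rather than produce occupancies outside
$[0,1]$ (with the bound satisfied the update is a convex combination, so
the bounds are preserved exactly).

Two further mechanisms mirror what single-crystal imaging actually shows:

* **Face-dependent ingress.** Real crystals load at different speeds
  through different faces ("well-defined layers" behind fast faces in cut
  crystals). `D_face` may be a named per-face vector; it is realised as a
  two-voxel near-surface diffusivity layer under each exposed face, with
  the interior at `max(D_face)`. This is the minimal mechanism that
  reproduces face-dependent layering without a full anisotropy model.
  No quantitative anisotropy ratios are established for the motivating
  system, so the default is all faces equal; anisotropy must be requested
  explicitly.
* **Defects.** Chips, bumps and scratches admit guest from several
  directions at once and redden first. Defects are modelled as extra
  surface voxels held at the bath occupancy.

Validation (all in the test suite): one-face uptake matches the 1-D
half-space solution $u = \mathrm{erfc}\!\big(x/2\sqrt{Dt}\big)$ (with the
origin at the held-layer voxel centre) to well under 2% RMS at 100
voxels/axis; short-time interior uptake follows $\sqrt{t}$ with a log-log
slope within 0.5 ± 0.05; all-faces uptake of a cube matches the exact
separable slab-series solution's initial rate to ~0.3%.

Uptake and release need not share a diffusivity -- the motivating
observations have complete infusion (~780 min) about four times faster
than substantial release (~3000 min) -- so uptake and release runs accept
separate parameter sets. A 100 µm cube with
$D_\text{uptake} = 3\times10^{-14}\,\mathrm{m^2/s}$ is ~99% infused at
780 min, which is the scale used in the uptake demonstrations;
release examples use $D$ near $1.5\times10^{-15}\,\mathrm{m^2/s}$.

## Optical rendering

Rendering mimics bright-field transmission: occupancy is path-integrated
along the view axis, converted to Beer-Lambert absorbance
$A_c = w_c\,\varepsilon \int u\,\mathrm{d}\ell$ per channel, and applied
to a bright background as $I_c = \mathrm{bg}_c e^{-A_c}$, followed by
seeded Gaussian camera noise and 8-bit quantisation. The channel weights
default to $w = (0.25, 1, 1)$: green and blue are absorbed strongly (the
crystal looks red), but red is attenuated *weakly rather than not at
all*. A red chromophore in realistic concentrations absorbs measurably
across the visible band, and this matters structurally: if the red
channel were perfectly transmitted, the red plane of every differential
image would be identically zero and the histogram pipeline's observable
would carry no signal at all. The weight 0.25 was fixed as a default at
design time and is exposed in `optics_model()`.

Default optics: extinction 0.03 per unit occupancy per µm (a fully
infused 100 µm crystal transmits ~5% of green/blue -- deep red but not
clipped), background (235, 235, 235), noise 2 counts, 8 px background
margin. All stochastic stages require an explicit seed; an unseeded call
with noise enabled is an error, and identical seeds give bit-identical
frames.

## Brownian ensembles

`simulate_walk()` generates free isotropic Brownian particles with
per-axis increment variance $2D\,\Delta t$; `estimate_D_msd()` inverts
$\mathrm{MSD} = q_i D t$. This provides ground truth for the
dimensionality constants ($q_i = 4$ in 2-D, 6 in 3-D, asserted within
three standard errors at $10^4$ particles) and a parameter-recovery check
of the estimator ($\hat D$ within three standard errors of the true
value, $\mathrm{sd}(\hat D)/D = \sqrt{2/(d\,n)}$).

# The histogram pipeline

`build_trace()` implements the reference-subtraction procedure: absolute
per-channel difference against the first frame (absolute, so infusion and
release share one code path and any offset common to both frames
cancels), red plane extracted verbatim (no luminance weighting -- the
chromophore is red), arithmetic mean over the frame. The mean is taken
over the full frame by default ("total pixels"); because background
pixels dilute the signal, an optional crystal mask (threshold of the
reference frame's green/blue mean at the midpoint of its range) is also
supported, and outputs record the mask area used. Which of the two a
given published trace used is generally ambiguous; both are first-class
here.

## The spot measure ω

$\omega$ is conventionally described only as the "linear change of the
spot that had diffused out", with no operational definition attached.
Operationally, here: in the first
post-reference frame and the frame nearest $t_D$, the differential red
image is median-filtered (3 × 3, to stop the frame maximum being a noise
order statistic under 8-bit quantisation), thresholded at half its
maximum, and the region's linear size is its **hydraulic diameter**
$4\,\mathrm{Area}/\mathrm{Perimeter}$ with a Crofton-corrected pixel
perimeter ($\pi/4$ × exposed-edge count). $\omega$ is the change in that
size between the two frames.

The hydraulic diameter -- not the area-equivalent circle diameter -- is
deliberate. For a compact disk-like spot the two coincide (both equal the
disk diameter, and a constructed disk fixture growing 20 → 43.2 µm yields
$\omega = 23.2$ µm either way). But a crystal releasing through all its
faces produces an *annular* spot: a band of depth $d$ along the rim. The
hydraulic diameter of such a band is $\approx 2d$, the diffusion
penetration scale that $D = \omega^2/4t_D$ expects; an area-equivalent
circle diameter is $\approx\sqrt{16\,L\,d/\pi}$, which is dominated by
the crystal size $L$ rather than by diffusion. Measured on synthetic
release runs, the area-equivalent variant over-estimated $D$ by up to
25× and did not even preserve rank order across different true $D$; the
hydraulic variant recovers $D$ within a factor of ~2 with correct
ordering, which is what the test suite asserts.

# Release kinetics

The release observable rises and flattens. It is fitted with a **capped
saturating-log model**

$$I(t) = \min\{A \ln(1 + t/\tau),\; P\},$$

chosen because the classical "logarithmic diffusion" approximation is
logarithmic at intermediate times but any real trace is bounded; the cap
$P$ is the plateau. The logarithmic approximation circulates without a
canonical closed form, so this form is this package's own choice; the
fit reports its RMSE so alternative forms can be compared, and result
files carry the model string. Fitting uses
damped Levenberg-Marquardt on log-parameters (positivity without box
constraints; the damping also tolerates the flat plateau gradient when
the cap is not binding). On noiseless samples of the model itself the fit
recovers $A$ and $\tau$ to better than 1%.

$t_D$ is the earliest time the *fitted* curve reaches half the *fitted*
plateau, $t_D = \tau\,(e^{P/2A} - 1)$ -- robust to truncated observation
windows, unlike "half of the last observed sample". It is scale
equivariant: scaling a trace scales $P$ but leaves $t_D$ unchanged.

**Known limitation.** When the observation window ends long before
depletion the trace is still in its $\sqrt{t}$ regime, which the
capped-log model mis-specifies; the fitted $\tau$ and $P$ then trade off
against each other and $t_D$ is unstable under resampling (doubling the
frame density can move the end-to-end $\hat D$ by tens of percent). The
factor-of-2 recovery asserted in the tests holds at the study's own
irregular frame schedule; sampling-robustness beyond that is not claimed.

# Sensing design calculations

Literature constants (0.33 mg/mg capacity, 11.2%/hr initial uptake,
10 ng/mL spectroscopic detection limit, cage/window/molecule geometry)
ship as a versioned JSON file with per-field provenance notes; they are
*never* used to calibrate the simulator.

* `capacity()` is exactly linear in MOF mass.
* `window_accessibility()` passes a rigid box through a circular aperture
  iff the larger of its two smallest dimensions fits (inclusive at
  equality). There is no standard passage criterion for a rigid box and
  a circular aperture; this is the minimal rule consistent with the B12
  box (1.41 × 1.83 × 1.14 nm)
  demonstrably entering through ≤ 1.7 nm windows while 1.3 nm windows are
  sub-molecular.
* `initial_uptake_rate()` fits a line over an early window and normalises
  by the saturation intensity (fraction per hour). Early uptake is a
  short section of a $\sqrt{t}$ law, so longer windows give lower rates
  (concavity) and larger crystals lower rates at fixed $D$ -- both
  asserted in tests.
* `saturation_ordering()` reports half-saturation times at canonical
  probes. The probes sit **one voxel inside** the Dirichlet-held surface
  layer: held voxels equal the bath value from $t = 0^+$ by construction,
  so literal surface voxels would all tie at zero and carry no ordering
  information. One voxel in, a corner fills from three sides, an edge
  from two, a face centre from one, and the strict ordering
  corner < edge < face < centre emerges, mirroring the observed
  corners-then-edges-then-faces-then-interior reddening (20, 60, 300,
  780 min in the motivating observations; the probe times themselves are not
  comparable to those figures, since probes sample single near-surface
  voxels while visible reddening integrates over depth). Probes whose
  faces are sealed are excluded; an already-saturated input gives all
  zeros and a vacuous (NA) ordering flag.

# Problem sizes and numerical choices

* Grids: 64³ for the end-to-end recovery runs (100 µm crystal, 1.56 µm
  voxels), 48³ for the ordering run, 32³ and bar geometries (200 × 6 × 6)
  for solver validation -- sizes at which the full suite runs in about a
  minute on one core while keeping fronts resolved (the erfc check uses
  ≥ 1.2 µm voxels against a 10 µm diffusion length).
* Time step: automatic at 0.99 × the stability bound unless set
  explicitly; simulation lands exactly on each requested sample time by
  shortening the final step.
* Ties/degenerate inputs: duplicate manifest timestamps are errors;
  unsorted manifests are sorted with a warning; identically-zero traces
  refuse to fit; a no-change sequence has no measurable spot and errors.
* Units: µm and minutes at the user surface, SI for every reported $D$;
  all conversions route through one audited function, `convert_unit()`.

# What passing tests do and do not show

The generator emulates: faceted geometry, Dirichlet bath coupling,
face-dependent ingress, surface defects, Beer-Lambert colour, camera
noise and 8-bit quantisation, and irregular frame schedules. It does
*not* emulate: molecular-scale pore transport (cages and windows enter
only through the geometric accessibility gate), guest trapping or
host-guest binding (the motivating release stops while the crystal is
still visibly coloured -- a trapped fraction this pure-diffusion
simulator cannot produce), crystal growth/dissolution, refraction,
scattering, polarisation, illumination drift, or registration error.
Passing the suite therefore demonstrates internal consistency of
solver, optics, pipeline and estimators -- not that the FRAP-style
formula is unbiased on arbitrary real crystals.
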